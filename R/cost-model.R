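#' Specification for tiered genetic-testing cost comparison
#'
#' Per-trio test prices and stage-outcome counts for comparing a
#' panel-first tiered strategy with exome-only testing.  Defaults encode
#' a two-tier history in which 139 trios were resolved by a targeted gene
#' panel, 10 more by whole-exome sequencing after a negative panel, and
#' 92 remained negative after both tests (241 evaluated trios; patients
#' lost to follow-up after a negative panel are excluded from cost
#' evaluation).  Default prices: $315 per panel trio, $945 per exome
#' trio.
#'
#' @param panel_price,wes_price price per trio of the panel and of the
#'   exome test.
#' @param n_panel_pos,n_wes_pos,n_both_neg stage-outcome counts.
#' @return a `crs_cost_spec` list, with `n_evaluated` filled in.
#' @export
strategy_cost_spec <- function(panel_price = 315, wes_price = 945,
                               n_panel_pos = 139, n_wes_pos = 10,
                               n_both_neg = 92) {
  if (panel_price < 0 || wes_price < 0) {
    crs_abort("prices must be non-negative", "crstrio_config_error")
  }
  counts <- c(n_panel_pos, n_wes_pos, n_both_neg)
  if (any(counts < 0) || any(counts != floor(counts))) {
    crs_abort("counts must be non-negative integers", "crstrio_config_error")
  }
  structure(list(
    panel_price = panel_price, wes_price = wes_price,
    n_panel_pos = n_panel_pos, n_wes_pos = n_wes_pos,
    n_both_neg = n_both_neg,
    n_evaluated = n_panel_pos + n_wes_pos + n_both_neg
  ), class = "crs_cost_spec")
}

cost_breakdown <- function(spec, group_unit_costs) {
  counts <- c(spec$n_panel_pos, spec$n_wes_pos, spec$n_both_neg)
  group_totals <- counts * group_unit_costs
  names(group_totals) <- c("panel_pos", "wes_pos", "both_neg")
  total <- sum(group_totals)
  if (spec$n_evaluated == 0) {
    crs_abort("per-trio mean undefined for zero evaluated trios",
              "crstrio_config_error")
  }
  list(
    group_totals = group_totals,
    total = total,
    per_trio = round_half_up(total / spec$n_evaluated)
  )
}

#' Cost of the panel-first tiered strategy
#'
#' Panel-resolved trios pay only the panel; trios that went on to exome
#' sequencing (whether it resolved them or not) pay panel plus exome.
#' The per-trio mean is the grand total over evaluated trios, rounded
#' half-up to whole currency units.
#'
#' @param spec a [strategy_cost_spec()].
#' @return list: `group_totals` (named, panel_pos/wes_pos/both_neg),
#'   `total`, `per_trio`.
#' @export
cost_panel_first <- function(spec = strategy_cost_spec()) {
  cost_breakdown(spec, c(spec$panel_price,
                         spec$panel_price + spec$wes_price,
                         spec$panel_price + spec$wes_price))
}

#' Cost of the exome-only strategy
#'
#' Every evaluated trio pays the exome price once; because the panel's
#' target genes are a subset of the exome, the diagnostic yield is the
#' same as panel-first.
#'
#' @param spec a [strategy_cost_spec()].
#' @return list as in [cost_panel_first()].
#' @export
cost_wes_only <- function(spec = strategy_cost_spec()) {
  cost_breakdown(spec, rep(spec$wes_price, 3))
}

#' Compare tiered and exome-only strategies
#'
#' @param spec a [strategy_cost_spec()].
#' @return list: `per_trio_panel_first`, `per_trio_wes_only`,
#'   `saving_per_trio` (absolute difference), `saving_percent`
#'   (percentage of the exome-only per-trio cost, rounded half-up to one
#'   decimal).
#' @export
compare_strategies <- function(spec = strategy_cost_spec()) {
  pf <- cost_panel_first(spec)
  wo <- cost_wes_only(spec)
  saving <- wo$per_trio - pf$per_trio
  list(
    per_trio_panel_first = pf$per_trio,
    per_trio_wes_only = wo$per_trio,
    saving_per_trio = saving,
    saving_percent = round_half_up(100 * saving / wo$per_trio, 1)
  )
}

#' Cost of a general k-tier testing strategy
#'
#' Generalizes the two-tier comparison: tests are run in order, each trio
#' stops after the first tier that resolves it, and trios unresolved by
#' every tier pay for all of them.  The two built-in strategies are the
#' presets `cost_panel_first()` (tiers panel, exome) and
#' `cost_wes_only()` (single tier).
#'
#' @param prices numeric vector of per-trio prices, one per tier, in
#'   testing order.
#' @param n_pos_by_tier integer vector, trios first resolved at each
#'   tier.
#' @param n_all_negative trios unresolved after the last tier.
#' @return list: `group_totals` (one per tier plus `all_negative`),
#'   `total`, `per_trio`.
#' @export
cost_tiered <- function(prices, n_pos_by_tier, n_all_negative) {
  if (length(prices) != length(n_pos_by_tier)) {
    crs_abort("one positive count per tier is required",
              "crstrio_config_error")
  }
  if (any(prices < 0) || any(n_pos_by_tier < 0) || n_all_negative < 0) {
    crs_abort("prices and counts must be non-negative",
              "crstrio_config_error")
  }
  cum_price <- cumsum(prices)
  group_totals <- c(n_pos_by_tier * cum_price,
                    n_all_negative * cum_price[length(cum_price)])
  names(group_totals) <- c(sprintf("tier%d_pos", seq_along(prices)),
                           "all_negative")
  n_eval <- sum(n_pos_by_tier) + n_all_negative
  if (n_eval == 0) {
    crs_abort("per-trio mean undefined for zero evaluated trios",
              "crstrio_config_error")
  }
  total <- sum(group_totals)
  list(group_totals = group_totals, total = total,
       per_trio = round_half_up(total / n_eval))
}
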