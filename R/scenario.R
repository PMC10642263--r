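#' Insurance co-payment scenario
#'
#' Re-runs the base case with selected drug prices multiplied by their
#' co-payment fraction, i.e. the share of the listed price that enters the
#' modelled (payer-perspective) cost. The second-line therapy cost is
#' treated as capecitabine, the guideline oral second-line agent, so a
#' `capecitabine` rate rescales `costs/drugs/second_line`.
#'
#' @param config An `npccea_config`.
#' @param rates Named list/vector of co-payment fractions in `[0, 1]`; names
#'   must be drugs with configured costs (`tislelizumab`, `gemcitabine`,
#'   `cisplatin`, `second_line`) or the alias `capecitabine`. Defaults to
#'   the configuration's `scenario$copayment` block (gemcitabine 20%,
#'   cisplatin 0%, capecitabine 5%).
#' @return A list of class `base_case` for the adjusted configuration (the
#'   comparison is in `$comparison`).
#' @export
copayment_scenario <- function(config = default_config(),
                               rates = config$scenario$copayment) {
  rates <- unlist(rates)
  if (is.null(names(rates)) || any(!nzchar(names(rates))))
    stop("`rates` must be named by drug")
  if (any(rates < 0 | rates > 1)) stop("co-payment rates must be in [0, 1]")
  for (drug in names(rates)) {
    key <- if (drug == "capecitabine") "second_line" else drug
    if (is.null(config$costs$drugs[[key]]))
      stop("unknown drug in co-payment rates: '", drug, "'")
    # scale the whole (base, low, high) triple so ranges stay coherent
    entry <- config$costs$drugs[[key]]
    entry$base <- entry$base * rates[[drug]]
    entry$low <- entry$low * rates[[drug]]
    entry$high <- entry$high * rates[[drug]]
    config$costs$drugs[[key]] <- entry
  }
  run_base_case(config)
}
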