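#' ChIP-qPCR percent input
#'
#' `% input = 100 * 2^-(Ct_IP - Ct_input_adj)`, where the input Ct is
#' optionally adjusted for the fraction of chromatin reserved as input:
#' `Ct_input_adj = Ct_input - log2(dilution factor)`. The default factor of
#' 1 applies no adjustment, i.e. the formula exactly as printed on qPCR
#' instruments. Strictly decreasing in `ct_ip`, strictly increasing in
#' `ct_input`.
#'
#' @param ct_ip Ct of the immunoprecipitated sample (finite cycles).
#' @param ct_input Ct of the input sample.
#' @param input_dilution_factor Ratio >= 1 by which the input underrepresents
#'   total chromatin (e.g. 60 when 5 uL of 300 uL is reserved).
#' @return Percent input (percentage points).
#' @examples
#' percent_input(25, 25)          # 100
#' percent_input(26, 25)          # 50: one cycle later halves the estimate
#' @export
percent_input <- function(ct_ip, ct_input, input_dilution_factor = 1) {
  stopifnot(is.finite(ct_ip), is.finite(ct_input))
  if (any(input_dilution_factor < 1))
    stop("input_dilution_factor must be >= 1")
  adj_input <- ct_input - log2(input_dilution_factor)
  100 * 2^(-(ct_ip - adj_input))
}

#' A qPCR measurement
#'
#' Pairs a target-gene Ct with the Ct of the internal reference (e.g.
#' GAPDH) under one condition.
#'
#' @param ct_target Target-gene Ct (finite, > 0).
#' @param ct_reference Reference-gene Ct.
#' @param condition Optional condition label.
#' @return A list of class `qpcr_measurement`.
#' @export
qpcr_measurement <- function(ct_target, ct_reference, condition = "") {
  stopifnot(is.finite(ct_target), ct_target > 0,
            is.finite(ct_reference), ct_reference > 0)
  structure(list(ct_target = ct_target, ct_reference = ct_reference,
                 condition = condition), class = "qpcr_measurement")
}

#' Relative abundance by the 2^-ddCt method
#'
#' Fold change of the target transcript in `treated` relative to `control`,
#' normalized to the internal reference:
#' `dCt = Ct_target - Ct_reference` per condition,
#' `ddCt = dCt_treated - dCt_control`, returning `2^-ddCt`.
#' Identical measurements give 1; swapping treated and control gives the
#' reciprocal.
#'
#' @param treated,control [qpcr_measurement()] objects (or lists with
#'   `ct_target` and `ct_reference`).
#' @return Dimensionless fold change.
#' @examples
#' m <- qpcr_measurement(20, 18)
#' relative_abundance_ddct(m, qpcr_measurement(22, 18))  # 4
#' @export
relative_abundance_ddct <- function(treated, control) {
  dct_t <- treated$ct_target - treated$ct_reference
  dct_c <- control$ct_target - control$ct_reference
  stopifnot(is.finite(dct_t), is.finite(dct_c))
  2^(-(dct_t - dct_c))
}
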