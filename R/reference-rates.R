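# Bundled reference estimates of the transition rates (percent units), one
# column per clinical group.  Stored in percent to mirror the canonical CSV
# layout; converted to fractions only when a transition_rates object is built.
.reference_groups <- c("controls", "RRMS_naive", "RRMS_NAT", "RRMS_ALEM", "SuS")

.reference_rates_pct <- local({
  rows <- list(
    CD4 = rbind(
      alpha1 = c(0.111389,   0.586281, 0.0532484,  0.796713, 0.200412),
      alpha2 = c(0.0911057,  0.472904, 0.104328,   0.579225, 0.14176),
      beta1  = c(6.36074,    6.97785,  5.56686,   16.5061,   9.53956),
      beta2  = c(4.94663,    5.36697,  9.84513,   10.7709,   6.32671)),
    CD8 = rbind(
      alpha1 = c(0.120849,   0.743036, 0.16279,    1.38373,  0.144033),
      alpha2 = c(0.280367,   1.68937,  0.383813,   2.36217,  0.196247),
      beta1  = c(10.5938,   12.6372,   8.48535,   22.0888,  22.3179),
      beta2  = c(19.7744,   22.4608,  16.7073,    27.9459,  23.472)),
    B = rbind(
      alpha1 = c(0.00624261, 0.163174, 0.00734096, 0.114144, 0.034936),
      alpha2 = c(0.517731,   2.05505,  0.756185,   4.19525,  0.628489),
      beta1  = c(0.512537,   0.706717, 0.539675,   0.290181, 1.07631),
      beta2  = c(29.9383,    8.32669, 35.9123,    10.0614,  16.3201)),
    NK = rbind(
      alpha1 = c(0.00960978, 0.083438, 0.00982681, 0.143154, 0.012265),
      alpha2 = c(0.0035751,  0.008764, 0.00583337, 0.013084, 0.007612),
      beta1  = c(93.6461,   92.5525,  88.5722,    78.6259,  92.6465),
      beta2  = c(25.7994,    8.89219, 34.558,      6.71746, 36.57)))
  df <- do.call(rbind, lapply(names(rows), function(ct) {
    m <- rows[[ct]]
    data.frame(cell_type = ct, rate = rownames(m), m, row.names = NULL)
  }))
  names(df) <- c("cell_type", "rate", .reference_groups)
  df
})

#' Bundled reference transition-rate estimates
#'
#' Returns the packaged reference estimate of the four transition rates for
#' one lymphocyte lineage and one clinical group, converted from percent to
#' fractions.  The table covers non-inflammatory controls, treatment-naive
#' relapsing-remitting MS (`RRMS_naive`), natalizumab- and
#' alemtuzumab-treated RRMS (`RRMS_NAT`, `RRMS_ALEM`), and Susac syndrome
#' (`SuS`), for CD4 and CD8 T cells, B cells and NK cells.
#'
#' These values serve as ground truth for the synthetic-cohort generator and
#' as worked examples throughout the package.
#'
#' @param cell_type One of `"CD4"`, `"CD8"`, `"B"`, `"NK"`.
#' @param group One of `"controls"`, `"RRMS_naive"`, `"RRMS_NAT"`,
#'   `"RRMS_ALEM"`, `"SuS"`.
#' @return A [transition_rates()] object (rates as fractions).
#' @examples
#' reference_rates("CD8", "controls")
#' @export
reference_rates <- function(cell_type, group) {
  if (length(cell_type) != 1L || !cell_type %in% .cell_types)
    stop(sprintf("unknown cell_type %s; valid: %s",
                 deparse(cell_type), paste(.cell_types, collapse = ", ")),
         call. = FALSE)
  if (length(group) != 1L || !group %in% .reference_groups)
    stop(sprintf("unknown group %s; valid: %s",
                 deparse(group), paste(.reference_groups, collapse = ", ")),
         call. = FALSE)
  sub <- .reference_rates_pct[.reference_rates_pct$cell_type == cell_type, ]
  v <- sub[[group]] / 100
  names(v) <- sub$rate
  transition_rates(v[["alpha1"]], v[["alpha2"]], v[["beta1"]], v[["beta2"]],
                   cell_type = cell_type, group = group)
}
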