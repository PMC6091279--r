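# Small in-code fixtures shared across test files.

# filled square mask of side `s` inside an n x n canvas
square_mask <- function(s, n = s) {
  m <- matrix(FALSE, n, n)
  off <- floor((n - s) / 2)
  m[(off + 1):(off + s), (off + 1):(off + s)] <- TRUE
  m
}

# condition_means object without going through a measurement table
cm_fixture <- function(accession, treatment, dw, l1, n = 12L) {
  structure(
    list(accession_id = accession, treatment = treatment,
         mean_DW_mg = dw, mean_L1_mm = l1, n_plants = n,
         n_missing_dw = 0L, n_missing_l1 = 0L),
    class = "condition_means"
  )
}

# the five indices printed for the screen's worked example
printed_bei_table <- function() {
  data.frame(
    accession_id = c("CR2262", "CR3195", "CR2280", "CR2267", "CR2285"),
    bei = c(0.0005, 0.10, 0.7039, 0.7059, 0.8800)
  )
}

# measurement table for one accession with explicit replicate values
measurements_fixture <- function(accession = "A1", dw_b0, dw_b1,
                                 l1_b0 = rep(50, length(dw_b0)),
                                 l1_b1 = rep(50, length(dw_b1))) {
  rbind(
    data.frame(accession_id = accession, treatment = "B0",
               replicate = seq_along(dw_b0), DW_mg = dw_b0, L1_mm = l1_b0),
    data.frame(accession_id = accession, treatment = "B1",
               replicate = seq_along(dw_b1), DW_mg = dw_b1, L1_mm = l1_b1)
  )
}
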