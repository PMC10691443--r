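# Shared fixture builders; everything is generated in code at test time.

# A one-line, few-pair design for fast simulations.
tiny_design <- function(pair_ids = c(1, 4), n_replicates = 2, line = "GBM8") {
  reg <- drug_pair_registry()
  study_design(registry = reg[reg$cell_line == line &
                                reg$pair_id %in% pair_ids, ],
               n_replicates = n_replicates)
}

# The desk-scale design used by the heavier recovery experiments:
# 1 cell line x 4 drug pairs x technical duplicates, 6x6 grids.
desk_design <- function() tiny_design(pair_ids = c(1, 4, 9, 15))

# Standard six-dose axis (3-fold from 5 uM) in ascending order with the
# leading zero, as used throughout the checkerboard layout.
ascending_axis <- function(max_conc = 5) {
  rev(dilution_series(max_conc, 3, 5)$values)
}

# A noiseless observed matrix generated from two Hill monotherapy curves
# under exact Bliss independence (the additive null on the viability scale).
bliss_true_matrix <- function(hA, hB, d1 = ascending_axis(),
                              d2 = ascending_axis(), ...) {
  v <- outer(hill_viability(hA, d1), hill_viability(hB, d2)) / 100
  dose_matrix(v, d1, d2, ...)
}
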