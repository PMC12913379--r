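# shared small fixtures, built in code

random_gct <- function(nr = 5, nc = 4, seed = 1, with_na = FALSE) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc), nr, nc,
              dimnames = list(sprintf("G%03d", 1:nr), sprintf("S%02d", 1:nc)))
  if (with_na) m[sample(length(m), max(1, length(m) %/% 10))] <- NA
  rdesc <- data.frame(id = rownames(m), gene_symbol = rownames(m),
                      invariant_level = 0L)
  cdesc <- data.frame(id = colnames(m), plate_id = "P1",
                      pert_id = sprintf("cp%d", seq_len(nc)))
  gct(m, rdesc = rdesc, cdesc = cdesc)
}

small_screen <- function(seed = 3, n_compounds = 6, n_cell_lines = 2,
                         n_genes = 120, active_fraction = 0.5, ...) {
  cfg <- screen_config(n_cell_lines = n_cell_lines,
                       n_compounds = n_compounds, n_genes = n_genes,
                       invariant_per_level = 3, vehicle_per_plate = 6,
                       plate_capacity = n_compounds * 6 + 6,
                       module_size = 12, active_fraction = active_fraction,
                       ...)
  simulate_screen(cfg, seed = seed)
}
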