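#' Configuration of a synthetic bead-level screen
#'
#' Defaults emulate a full chemical-genetic screen: 6 cell lines exposed to
#' 60 compounds at 2 concentrations (0.5 uM, 5 uM) in 3 biological
#' replicates, profiled on a 467-gene panel with an 80-probe invariant ladder
#' (8 probes per ladder level), one 384-well detection plate per cell line
#' with 24 vehicle-control wells.  Compound effects are planted on random
#' gene modules in z-score units; the high dose scales the effect by
#' `dose_multiplier`.
#'
#' @param n_cell_lines,n_compounds,n_replicates screen dimensions.
#' @param doses character vector of dose strings.
#' @param time exposure time string.
#' @param n_genes panel size (non-invariant genes).
#' @param n_invariant_levels,invariant_per_level invariant ladder shape.
#' @param n_beads beads measured per gene per well.
#' @param plate_capacity wells per detection plate.
#' @param vehicle_per_plate vehicle-control wells added to each plate.
#' @param module_size genes affected by each active compound.
#' @param effect_z planted effect size at the low dose, in robust-z units.
#' @param dose_multiplier effect multiplier for each successive dose.
#' @param active_fraction fraction of compounds given a nonzero effect.
#' @param bead_sd,well_sd log2-scale noise standard deviations (bead-level
#'   and well-level).
#' @param cell_sd per-(cell line, gene) baseline offset sd (log2).
#' @param distortion_scale,distortion_shift ranges of the per-well monotone
#'   affine distortion a*x + b applied on the log2 scale (undone by invariant
#'   calibration).
#' @return list of class `screen_config`.
#' @export
screen_config <- function(n_cell_lines = 6, n_compounds = 60,
                          n_replicates = 3, doses = c("0.5 uM", "5 uM"),
                          time = "24 h", n_genes = 467,
                          n_invariant_levels = 10, invariant_per_level = 8,
                          n_beads = 3, plate_capacity = 384,
                          vehicle_per_plate = 24, module_size = 20,
                          effect_z = 4, dose_multiplier = 1.5,
                          active_fraction = 0.8, bead_sd = 0.2,
                          well_sd = 0.1, cell_sd = 0.3,
                          distortion_scale = c(0.9, 1.1),
                          distortion_shift = c(-1, 1)) {
  cfg <- as.list(environment())
  n_treated <- n_compounds * length(doses) * n_replicates
  per_plate <- plate_capacity - vehicle_per_plate
  if (per_plate < n_replicates)
    stop("plate capacity too small for the requested replicates")
  cfg$plates_per_cell <- ceiling(n_treated / per_plate)
  structure(cfg, class = "screen_config")
}

.well_names <- function(n) {
  rows <- LETTERS[1:16]
  cols <- sprintf("%02d", 1:24)
  grid <- as.vector(t(outer(rows, cols, paste0)))
  if (n > length(grid)) stop("more wells than a 384-well plate holds")
  grid[seq_len(n)]
}

#' Simulate a bead-level screen with known ground truth
#'
#' Draws bead fluorescence as 2^(baseline + cell-line offset + planted
#' compound effect + well noise), passes it through a per-well monotone
#' affine distortion on the log2 scale (which the invariant calibration must
#' undo), and adds log-normal bead noise.  Vehicle wells carry no compound
#' effect.  Planted effects are expressed in robust-z units and converted to
#' log2 shifts through the implied per-gene plate standard deviation
#' sqrt(well_sd^2 + bead_sd^2 / n_beads).
#'
#' Identical (config, seed) pairs reproduce identical outputs.
#'
#' @param config a [screen_config].
#' @param seed integer RNG seed.
#' @return list of class `screen_sim`: `beads` (data.frame: plate_id, well,
#'   bead_barcode, fluorescence_intensity), `samples` (a [sample_table]),
#'   `probes` (a [probe_table]), `truth` (class `screen_truth`: baselines,
#'   module map with per-gene signs, per-compound effect size and active
#'   flag, noise parameters, seed).
#' @export
simulate_screen <- function(config = screen_config(), seed = 1) {
  stopifnot(inherits(config, "screen_config"))
  set.seed(seed)
  cfg <- config
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  inv_levels <- rep(seq_len(cfg$n_invariant_levels),
                    each = cfg$invariant_per_level)
  inv_genes <- sprintf("INV%02d_%d", inv_levels,
                       sequence(rep(cfg$invariant_per_level,
                                    cfg$n_invariant_levels)))
  all_genes <- c(genes, inv_genes)
  probes <- probe_table(gene_id = all_genes,
                        bead_barcode = sprintf("BC%04d",
                                               seq_along(all_genes)),
                        invariant_level = c(rep(0L, cfg$n_genes), inv_levels),
                        panel = "synthetic")
  ref <- invariant_reference(seq_len(cfg$n_invariant_levels))
  baseline <- c(stats::runif(cfg$n_genes, 4, 14),
                log2(ref$canonical_value + 1)[inv_levels])
  names(baseline) <- all_genes
  cells <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))
  compounds <- sprintf("CPD%03d", seq_len(cfg$n_compounds))
  n_active <- round(cfg$active_fraction * cfg$n_compounds)
  active <- seq_len(cfg$n_compounds) <= n_active
  modules <- lapply(seq_len(cfg$n_compounds), function(i) {
    if (!active[i]) return(data.frame(gene_id = character(0),
                                      sign = numeric(0)))
    g <- sample(genes, cfg$module_size)
    data.frame(gene_id = g,
               sign = sample(c(-1, 1), cfg$module_size, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  names(modules) <- compounds
  sigma_plate <- sqrt(cfg$well_sd^2 + cfg$bead_sd^2 / cfg$n_beads)
  cell_offset <- matrix(stats::rnorm(length(genes) * cfg$n_cell_lines,
                                     sd = cfg$cell_sd),
                        length(genes), cfg$n_cell_lines,
                        dimnames = list(genes, cells))

  # ---- plate layout -------------------------------------------------------
  samp <- list()
  for (ci in seq_along(cells)) {
    treated <- expand.grid(rep = seq_len(cfg$n_replicates),
                           dose = cfg$doses, pert = compounds,
                           stringsAsFactors = FALSE)
    per_plate <- cfg$plate_capacity - cfg$vehicle_per_plate
    treated$plate_ord <- ceiling(seq_len(nrow(treated)) / per_plate)
    for (p in unique(treated$plate_ord)) {
      tp <- treated[treated$plate_ord == p, , drop = FALSE]
      plate_id <- sprintf("%s_P%02d", cells[ci], p)
      n_t <- nrow(tp)
      wells <- .well_names(n_t + cfg$vehicle_per_plate)
      samp[[length(samp) + 1L]] <- data.frame(
        plate_id = plate_id,
        well = wells,
        pert_id = c(tp$pert, rep("DMSO", cfg$vehicle_per_plate)),
        pert_type = c(rep("CP", n_t), rep("CTRL", cfg$vehicle_per_plate)),
        pert_dose = c(tp$dose, rep("0 uM", cfg$vehicle_per_plate)),
        pert_time = cfg$time,
        cell_id = cells[ci],
        stringsAsFactors = FALSE)
    }
  }
  samp <- do.call(rbind, samp)
  samp$sample_id <- sprintf("S%05d", seq_len(nrow(samp)))
  samples <- sample_table(samp$sample_id, samp$plate_id, samp$well,
                          samp$pert_id, samp$pert_type, samp$pert_dose,
                          samp$pert_time, samp$cell_id)

  # ---- expression truth per well (log2 scale) -----------------------------
  n_w <- nrow(samples)
  u <- matrix(baseline, length(all_genes), n_w,
              dimnames = list(all_genes, samples$sample_id))
  u[genes, ] <- u[genes, , drop = FALSE] +
    cell_offset[, match(samples$cell_id, cells), drop = FALSE]
  dose_idx <- match(samples$pert_dose, cfg$doses)
  for (w in which(samples$pert_type == "CP")) {
    mod <- modules[[samples$pert_id[w]]]
    if (!nrow(mod)) next
    eff_z <- cfg$effect_z * cfg$dose_multiplier^(dose_idx[w] - 1L)
    u[mod$gene_id, w] <- u[mod$gene_id, w] +
      mod$sign * eff_z * sigma_plate
  }
  u <- u + matrix(stats::rnorm(length(u), sd = cfg$well_sd), nrow(u))
  a <- stats::runif(n_w, cfg$distortion_scale[1L], cfg$distortion_scale[2L])
  b <- stats::runif(n_w, cfg$distortion_shift[1L], cfg$distortion_shift[2L])
  d <- sweep(sweep(u, 2L, a, `*`), 2L, b, `+`)

  # ---- expand to beads ----------------------------------------------------
  bead_blocks <- vector("list", cfg$n_beads)
  for (k in seq_len(cfg$n_beads)) {
    fi <- 2^(d + matrix(stats::rnorm(length(d), sd = cfg$bead_sd),
                        nrow(d))) - 1
    fi[fi < 0] <- 0
    bead_blocks[[k]] <- data.table::data.table(
      plate_id = rep(samples$plate_id, each = nrow(d)),
      well = rep(samples$well, each = nrow(d)),
      bead_barcode = rep(probes$bead_barcode, n_w),
      fluorescence_intensity = as.vector(fi))
  }
  beads <- data.table::rbindlist(bead_blocks)
  data.table::setorder(beads, plate_id, well, bead_barcode)
  truth <- structure(list(config = cfg, seed = seed, baseline = baseline,
                          modules = modules, active = stats::setNames(active,
                                                                      compounds),
                          effect_z = stats::setNames(
                            ifelse(active, cfg$effect_z, 0), compounds),
                          sigma_plate = sigma_plate,
                          cell_lines = cells, compounds = compounds),
                     class = "screen_truth")
  structure(list(beads = as.data.frame(beads), samples = samples,
                 probes = probes, truth = truth), class = "screen_sim")
}

#' Simulate a reference RNA-seq panel for probe-recall validation
#'
#' Generates (1) a panel measurement matrix for the screen's genes across
#' `n_cell_lines` reference cell lines and (2) a reference log2-RPKM matrix
#' containing the matched genes plus `n_decoy` independent decoy genes.  Each
#' matched reference row correlates with its panel row at target correlation
#' `target_r`; decoys are independent noise.  Decoy baselines are drawn from
#' U(0, 10), so a subset is lowly expressed.
#'
#' @param truth a `screen_truth` (for gene ids and baselines).
#' @param n_cell_lines number of reference cell lines (>= 3; default 96).
#' @param n_decoy number of decoy reference genes.
#' @param target_r target probe/reference correlation in [0, 1].
#' @param expr_sd across-cell-line expression sd (log2).
#' @param seed integer RNG seed.
#' @return list: `panel` (probes x cell lines), `rnaseq` (reference genes x
#'   cell lines, log2 scale).
#' @export
simulate_reference_rnaseq <- function(truth, n_cell_lines = 96,
                                      n_decoy = 2000, target_r = 0.9,
                                      expr_sd = 1, seed = 1) {
  stopifnot(inherits(truth, "screen_truth"), n_cell_lines >= 3)
  set.seed(seed)
  genes <- names(truth$baseline)
  genes <- genes[seq_len(truth$config$n_genes)]  # panel genes only
  cells <- sprintf("REF%02d", seq_len(n_cell_lines))
  n_g <- length(genes)
  s <- matrix(stats::rnorm(n_g * n_cell_lines, sd = expr_sd), n_g,
              dimnames = list(genes, cells))
  panel <- truth$baseline[genes] + s
  e <- matrix(stats::rnorm(n_g * n_cell_lines, sd = expr_sd), n_g)
  matched <- truth$baseline[genes] + target_r * s +
    sqrt(max(0, 1 - target_r^2)) * e
  decoys <- matrix(stats::rnorm(n_decoy * n_cell_lines, sd = expr_sd),
                   n_decoy,
                   dimnames = list(sprintf("DECOY%04d", seq_len(n_decoy)),
                                   cells))
  decoys <- stats::runif(n_decoy, 0, 10) + decoys
  rnaseq <- rbind(matched, decoys)
  rownames(rnaseq) <- c(genes, rownames(decoys))
  colnames(rnaseq) <- cells
  list(panel = panel, rnaseq = rnaseq)
}

#' Simulate a touchstone reference signature collection
#'
#' Generates level-5-style z-score signatures for a reference set of
#' perturbagens across the screen's cell lines: background noise signatures
#' of all perturbagen classes (CP/CTRL and, optionally, KD/OE), plus
#' optionally one knockdown that shares a chosen compound's planted gene
#' module (for planted-recovery tests of the similarity engine).
#'
#' @param truth a `screen_truth`.
#' @param n_reference_perts number of reference perturbagens (>= 10).
#' @param include_kdoe include KD/OE perturbagen classes.
#' @param planted_kd_for optional compound id from the screen; a KD signature
#'   sharing that compound's module (same signs, effect `effect_z`) is
#'   planted under pert_id `paste0("KD_", planted_kd_for)`.
#' @param effect_z planted module amplitude in z units.
#' @param seed integer RNG seed.
#' @return a level-5 [gct] of reference signatures, one column per
#'   (perturbagen, cell line).
#' @export
simulate_touchstone <- function(truth, n_reference_perts = 50,
                                include_kdoe = TRUE, planted_kd_for = NULL,
                                effect_z = 4, seed = 1) {
  stopifnot(inherits(truth, "screen_truth"), n_reference_perts >= 10)
  set.seed(seed)
  genes <- names(truth$baseline)[seq_len(truth$config$n_genes)]
  cells <- truth$cell_lines
  types <- if (include_kdoe) c("CP", "CTRL", "KD", "OE") else c("CP", "CTRL")
  perts <- sprintf("REFPERT%03d", seq_len(n_reference_perts))
  pert_type <- sample(types, n_reference_perts, replace = TRUE)
  if (!is.null(planted_kd_for)) {
    if (!planted_kd_for %in% names(truth$modules))
      stop("unknown compound: ", planted_kd_for)
    perts <- c(perts, paste0("KD_", planted_kd_for))
    pert_type <- c(pert_type, "KD")
  }
  grid <- expand.grid(cell_id = cells, pert = perts,
                      stringsAsFactors = FALSE)
  grid$pert_type <- pert_type[match(grid$pert, perts)]
  mat <- matrix(stats::rnorm(length(genes) * nrow(grid)), length(genes),
                nrow(grid), dimnames = list(genes, NULL))
  if (!is.null(planted_kd_for)) {
    mod <- truth$modules[[planted_kd_for]]
    idx <- which(grid$pert == paste0("KD_", planted_kd_for))
    mat[mod$gene_id, idx] <- mat[mod$gene_id, idx] + mod$sign * effect_z
  }
  ids <- sprintf("%s:%s", grid$pert, grid$cell_id)
  colnames(mat) <- ids
  cdesc <- data.frame(id = ids, pert_id = grid$pert,
                      pert_type = grid$pert_type, cell_id = grid$cell_id,
                      pert_dose = "10 uM", pert_time = "24 h",
                      stringsAsFactors = FALSE)
  gct(mat, cdesc = cdesc, level = 5L)
}

#' Serialize screen ground truth to JSON
#'
#' @param truth a `screen_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "screen_truth"))
  out <- list(seed = truth$seed,
              config = unclass(truth$config),
              sigma_plate = truth$sigma_plate,
              baseline = as.list(truth$baseline),
              active = as.list(truth$active),
              effect_z = as.list(truth$effect_z),
              modules = truth$modules,
              cell_lines = truth$cell_lines,
              compounds = truth$compounds)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
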