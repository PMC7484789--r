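# File io helpers (TSV/CSV/BED/JSON) and the end-to-end synthetic demo run.

#' Read / write tab-separated tables
#'
#' Thin wrappers with the package's conventions: header line, no row
#' names, no string-to-factor coercion.
#'
#' @param path File path.
#' @param df `data.frame` to write.
#' @return `read_tsv_table()` returns a `data.frame`; the writers return
#'   `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write BED intervals (0-based half-open)
#'
#' BED files are parsed with `rtracklayer::import()` and converted to the
#' package's BED-style data frame (`chrom`, `start`, `end`, optional
#' `state` from the BED name field); the writer emits plain 3- or 4-column
#' BED.
#'
#' @param path File path.
#' @param df BED-style `data.frame`.
#' @return `read_bed()` returns a BED-style `data.frame`; `write_bed()`
#'   returns `path` invisibly.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm) && !all(is.na(nm))) out$state <- as.character(nm)
  out
}

#' @rdname read_bed
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  cols <- df[c("chrom", "start", "end")]
  if ("state" %in% names(df)) cols$name <- df$state
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the full synthetic demonstration pipeline
#'
#' Generates one synthetic dataset per analysis stage (fibre population,
#' two-channel volume, locus traces for two conditions, gene/peak tables
#' with a state segmentation, growth plate), runs every stage of the
#' analysis on it, and writes all tables and summaries under `out_dir`
#' together with a `manifest.json` recording package version, parameters
#' and outputs. Deterministic: the same `seed` reproduces every file.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving all generators.
#' @return Invisibly, the manifest list.
#' @export
run_demo <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  pth <- function(...) file.path(out_dir, ...)
  manifest <- list(package = "rloopkit",
                   version = as.character(utils::packageVersion("rloopkit")),
                   seed = seed, outputs = character())
  add <- function(p) manifest$outputs <<- c(manifest$outputs, basename(p))

  # --- fibre stage: control vs stalled population -------------------------
  fib_ctrl <- sim_fibre_population(fibre_sim_config(
    n_tracks = 150, stall_prob = 0.05, seed = seed))
  fib_stall <- sim_fibre_population(fibre_sim_config(
    n_tracks = 150, stall_prob = 0.89, stall_severity = 0.6, seed = seed + 1L))
  add(write_tsv_table(fib_ctrl$tracks, pth("fibres_control.tsv")))
  add(write_tsv_table(fib_stall$pairs, pth("pairs_stalled.tsv")))
  speeds <- fork_speed(fib_ctrl$tracks$second_len_um,
                       fib_ctrl$tracks$second_pulse_min)
  fibre_summary <- list(
    speed_summary = as.list(summarize_speeds(speeds)),
    pct_symmetric_control = 100 * mean(
      classify_symmetry(fib_ctrl$pairs$left_um,
                        fib_ctrl$pairs$right_um) == "symmetric"),
    pct_symmetric_stalled = 100 * mean(
      classify_symmetry(fib_stall$pairs$left_um,
                        fib_stall$pairs$right_um) == "symmetric"),
    frac_gt2fold_stalled = as.numeric(fraction_fold_asymmetric(
      fib_stall$pairs$left_um, fib_stall$pairs$right_um)))

  # --- imaging stage ------------------------------------------------------
  vol <- sim_two_channel_volume(volume_sim_config(
    shape = c(48L, 48L, 48L), n_objects_a = 25, n_objects_b = 25,
    coloc_fraction = 0.5, seed = seed))
  oa <- segment_objects(vol$channel_a, threshold = 50,
                        voxel_size = vol$voxel_size, channel = "A")
  ob <- segment_objects(vol$channel_b, threshold = 50,
                        voxel_size = vol$voxel_size, channel = "B")
  cl <- coloc_by_voxel_overlap(oa, ob)
  objects <- rbind(oa, ob)
  objects$coloc <- c(rep(NA, nrow(oa)), cl$flags$coloc)
  add(write_tsv_table(objects, pth("objects.tsv")))
  ccf <- ccf_van_steensel(vol$channel_a, vol$channel_b, max_shift = 10)
  add(write_tsv_table(data.frame(shift = ccf$shifts, r = ccf$r),
                      pth("ccf.tsv")))
  coloc_summary <- c(cl$summary,
                     list(ccf_peak_shift = ccf$peak_shift,
                          ccf_verdict = ccf$verdict))

  # --- kinetics stage: tether vs control ----------------------------------
  fci_for <- function(cond_seed, mu) {
    cells <- lapply(seq_len(5L), function(i) {
      tr <- sim_locus_trace(kinetics_sim_config(
        formation_rate = 0.5, resolution_rate = mu,
        n0 = 25L, seed = cond_seed + i))
      fci_series(relative_intensity(tr$trace))$fci_log2
    })
    cells
  }
  conds <- list(control = fci_for(seed + 100L, 0.008),
                tethered = fci_for(seed + 200L, 0.03))
  verdict <- compare_turnover(conds)
  pooled <- lapply(conds, function(x) decompose_fci(unlist(x)))
  kin_summary <- list(
    frac_pos = lapply(pooled, `[[`, "frac_pos"),
    mean_total = lapply(pooled, `[[`, "mean_total"),
    verdict = verdict$verdict)
  tr0 <- sim_locus_trace(kinetics_sim_config(seed = seed + 300L))
  add(write_tsv_table(tr0$trace, pth("trace.tsv")))

  # --- genomics stage -----------------------------------------------------
  gen <- sim_gene_peak_table(genomics_sim_config(seed = seed))
  add(write_tsv_table(gen$genes, pth("genes.tsv")))
  add(write_bed(gen$peaks_ino80, pth("peaks_ino80.bed")))
  add(write_bed(gen$peaks_drip, pth("peaks_drip.bed")))
  add(write_bed(gen$states, pth("states.bed")))
  pw <- pairwise_correlation(gen$genes$ino80_abundance,
                             gen$genes$drip_abundance)
  pc <- partial_correlation(gen$genes$ino80_abundance,
                            gen$genes$drip_abundance, gen$genes$expression)
  bins <- make_genome_bins(c(chrS = gen$genome_length))
  cls <- classify_peak_overlap(gen$peaks_ino80, gen$peaks_drip, bins)
  class_regions <- lapply(split(bins, cls), GenomicRanges::reduce)
  class_regions <- class_regions[vapply(class_regions, length, 1L) > 0]
  enr <- state_enrichment(gen$states, class_regions)
  add(write_tsv_table(enr, pth("enrichment_matrix.tsv")))
  genomics_summary <- list(pairwise_r = pw$r, pairwise_p = pw$p_value,
                           partial_r = pc$r, partial_p = pc$p_value)

  # --- growth stage -------------------------------------------------------
  plate <- sim_growth_plate(effect_a = 0.2, effect_b = 0.9, interaction = 4,
                            n_wells = 6L, noise_sd = 0.02, seed = seed)
  utils::write.csv(plate, pth("plate.csv"), row.names = FALSE)
  add(pth("plate.csv"))
  m <- tapply(plate$growth, plate$condition, mean)
  pa <- percent_growth(m[["a"]], m[["control"]])
  pb <- percent_growth(m[["b"]], m[["control"]])
  v <- predicted_independent_growth(pa, pb)
  growth_summary <- list(
    pct_a = pa, pct_b = pb, v_predicted = v,
    observed_combined = 100 * m[["combined"]],
    rescue_fold = rescue_fold(100 * m[["combined"]], v))

  summary <- list(fibre = fibre_summary, coloc = coloc_summary,
                  kinetics = kin_summary, genomics = genomics_summary,
                  growth = growth_summary)
  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  add(pth("summary.json"))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
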