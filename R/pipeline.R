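#' Validate an end-to-end pipeline configuration
#'
#' @param fasta_path,regions_path Template inputs for [load_template()].
#' @param sample_sheet `data.frame` (or path to a TSV) with columns
#'   `sample_id`, `condition`, `replicate`, `path`; exactly two condition
#'   labels, each with >= 2 replicates.
#' @param reference_condition Which condition label is the reference; the
#'   other is the perturbed condition. Defaults to the first label in the
#'   sheet.
#' @param alpha Per-position t-test significance threshold.
#' @param q Pause-call top quantile.
#' @param window_unit Moving-average window for the whole unit (nt).
#' @param window_spacer Moving-average window within spacer regions (nt).
#' @param logo_window Context window width (odd).
#' @param umi_delim UMI delimiter in the BED name field.
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes all report tables, bedGraphs and a run manifest there.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(fasta_path, regions_path, sample_sheet,
                            reference_condition = NULL,
                            alpha = 0.05, q = 0.025,
                            window_unit = 200L, window_spacer = 75L,
                            logo_window = 21L, umi_delim = "#",
                            out_dir = NULL) {
  if (is.character(sample_sheet) && length(sample_sheet) == 1L) {
    if (!file.exists(sample_sheet)) stop("sample sheet not found: ", sample_sheet)
    sample_sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  }
  required <- c("sample_id", "condition", "replicate", "path")
  missing <- setdiff(required, names(sample_sheet))
  if (length(missing) > 0L) {
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  }
  conds <- unique(sample_sheet$condition)
  if (length(conds) != 2L) {
    stop("exactly 2 condition labels are required, found ", length(conds))
  }
  reps <- table(sample_sheet$condition)
  if (any(reps < 2L)) {
    stop(
      "condition(s) with fewer than 2 replicates: ",
      paste(names(reps)[reps < 2L], collapse = ", ")
    )
  }
  if (is.null(reference_condition)) {
    reference_condition <- conds[1L]
  }
  if (!reference_condition %in% conds) {
    stop("reference_condition '", reference_condition, "' is not in the sample sheet")
  }
  for (f in c(fasta_path, regions_path, sample_sheet$path)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  structure(
    list(
      fasta_path = fasta_path, regions_path = regions_path,
      sample_sheet = sample_sheet,
      reference_condition = reference_condition,
      perturbed_condition = setdiff(conds, reference_condition),
      alpha = alpha, q = q,
      window_unit = as.integer(window_unit),
      window_spacer = as.integer(window_spacer),
      logo_window = as.integer(logo_window),
      umi_delim = umi_delim, out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Run the full NET-seq occupancy analysis
#'
#' Executes dedup -> occupancy -> normalize -> replicate QC (Spearman, PCA)
#' -> per-position t-test -> spacer KS tests -> pause calling -> difference
#' logo, and (when `out_dir` is set) writes every report table, per-sample
#' bedGraphs and a run manifest with per-stage record counts.
#'
#' @param config A [pipeline_config()].
#' @return A result bundle: `template`, `tracks` (per condition),
#'   `spearman`, `pca`, `profiles`, `moving_averages`, `ttest`, `ks`,
#'   `pauses`, `pwms`, `logo`, `positions`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  template <- load_template(config$fasta_path, config$regions_path)
  sheet <- config$sample_sheet
  conds <- c(config$reference_condition, config$perturbed_condition)
  tracks <- stats::setNames(vector("list", 2L), conds)
  sample_counts <- list()
  for (i in seq_len(nrow(sheet))) {
    reads <- read_reads_bed(sheet$path[i], umi_delim = config$umi_delim)
    dd <- deduplicate_umis(reads)
    occ <- raw_occupancy(dd$reads, template, sheet$sample_id[i], sheet$condition[i])
    tracks[[sheet$condition[i]]] <- c(tracks[[sheet$condition[i]]],
                                      list(normalize_track(occ)))
    sample_counts[[length(sample_counts) + 1L]] <- data.frame(
      sample_id = sheet$sample_id[i], condition = sheet$condition[i],
      reads_in = nrow(reads), duplicates_removed = dd$n_removed,
      wrong_strand_dropped = occ$dropped$wrong_strand,
      out_of_bounds_dropped = occ$dropped$out_of_bounds,
      reads_counted = occ$n_reads, stringsAsFactors = FALSE
    )
  }
  all_tracks <- c(tracks[[1L]], tracks[[2L]])
  qc_spearman <- spearman_matrix(all_tracks)
  qc_pca <- pca_samples(all_tracks)
  profiles <- lapply(tracks, median_profile)
  ma_unit <- lapply(profiles, function(p) moving_average(p$values, config$window_unit))
  sp <- template$regions[template$regions$region_class == "spacer", , drop = FALSE]
  ma_spacer <- lapply(profiles, function(p) {
    out <- lapply(seq_len(nrow(sp)), function(i) {
      moving_average(slice_region(p$values, sp[i, ]), config$window_spacer)
    })
    stats::setNames(out, sp$name)
  })
  tt <- per_position_ttest(tracks[[config$reference_condition]],
                           tracks[[config$perturbed_condition]],
                           alpha = config$alpha)
  ks <- spacer_ks_tests(profiles[[config$reference_condition]],
                        profiles[[config$perturbed_condition]], template)
  pauses <- lapply(profiles, call_pauses, template = template, q = config$q)
  contexts <- lapply(pauses, extract_contexts, template = template,
                     W = config$logo_window)
  pwms <- lapply(names(contexts), function(cond) {
    build_pwm(contexts[[cond]], condition = cond)
  })
  names(pwms) <- names(contexts)
  logo <- difflogo(pwms[[config$perturbed_condition]],
                   pwms[[config$reference_condition]])
  ptab <- positions_table(template, all_tracks, profiles)
  manifest <- list(
    package = "netpause",
    version = as.character(utils::packageVersion("netpause")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(
      reference_condition = config$reference_condition,
      perturbed_condition = config$perturbed_condition,
      alpha = config$alpha, q = config$q,
      window_unit = config$window_unit, window_spacer = config$window_spacer,
      logo_window = config$logo_window, umi_delim = config$umi_delim
    ),
    samples = do.call(rbind, sample_counts),
    untestable_positions = sum(!tt$tests$testable),
    contexts_dropped = vapply(contexts, function(x) x$n_dropped, integer(1))
  )
  bundle <- list(
    template = template, tracks = tracks, spearman = qc_spearman,
    pca = qc_pca, profiles = profiles,
    moving_averages = list(unit = ma_unit, spacer = ma_spacer),
    ttest = tt, ks = ks, pauses = pauses, pwms = pwms, logo = logo,
    positions = ptab, manifest = manifest
  )
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(bundle, config)
  }
  bundle
}

# Writes all stage outputs; tables are deterministic for identical inputs
# (the timestamp lives only in the manifest).
write_pipeline_outputs <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  template <- bundle$template
  for (cond in names(bundle$tracks)) {
    for (t in bundle$tracks[[cond]]) {
      write_bedgraph(t$values, template, out(paste0(t$sample_id, ".norm.bedgraph")))
    }
    write_bedgraph(bundle$profiles[[cond]]$values, template,
                   out(paste0("median_", cond, ".bedgraph")))
    write_bedgraph(bundle$moving_averages$unit[[cond]], template,
                   out(paste0("moving_average_", cond, ".bedgraph")))
  }
  sm <- as.data.frame(bundle$spearman)
  sm <- cbind(sample_id = rownames(bundle$spearman), sm)
  write_tsv(sm, out("spearman.tsv"))
  write_tsv(bundle$pca$coordinates, out("pca.tsv"))
  write_tsv(
    data.frame(component = paste0("PC", seq_along(bundle$pca$var_explained)),
               var_explained = bundle$pca$var_explained),
    out("pca_variance.tsv")
  )
  tt <- bundle$ttest$tests
  tt$position <- tt$position + 1L # report tables are 1-based inclusive
  write_tsv(tt, out("position_tests.tsv"))
  write_tsv(bundle$ks, out("spacer_ks.tsv"))
  for (cond in names(bundle$pauses)) {
    ps <- bundle$pauses[[cond]]
    ptab <- data.frame(
      position = ps$positions + 1L,
      median_occupancy = bundle$profiles[[cond]]$values[ps$positions + 1L]
    )
    ptab <- ptab[order(-ptab$median_occupancy, ptab$position), ]
    ptab$rank <- seq_len(nrow(ptab))
    write_tsv(ptab, out(paste0("pauses_", cond, ".tsv")))
    pwm <- bundle$pwms[[cond]]
    pw <- as.data.frame(t(pwm$matrix))
    pw <- cbind(offset = seq_len(pwm$width) - 1L - (pwm$width - 1L) %/% 2L, pw)
    write_tsv(pw, out(paste0("pwm_", cond, ".tsv")))
  }
  write_tsv(difflogo_table(bundle$logo), out("difflogo.tsv"))
  write_tsv(bundle$positions, out("positions_table.tsv"))
  manifest <- bundle$manifest
  manifest$samples <- as.list(as.data.frame(manifest$samples))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' Normalized tracks straight from a simulation
#'
#' Convenience for in-memory analysis of [simulate_reads()] output without a
#' BED round trip: deduplicates each replicate, counts LNT occupancy and
#' normalizes.
#'
#' @param sim A `netseq_sim`.
#' @return List with one element per condition, each a list of
#'   `normalized_track`s; per-replicate dedup counts are attached as the
#'   `"dedup_removed"` attribute.
#' @export
sim_tracks <- function(sim) {
  stopifnot(inherits(sim, "netseq_sim"))
  removed <- list()
  out <- lapply(stats::setNames(names(sim$reads), names(sim$reads)), function(cond) {
    lapply(seq_along(sim$reads[[cond]]), function(r) {
      dd <- deduplicate_umis(sim$reads[[cond]][[r]])
      removed[[paste(cond, r)]] <<- dd$n_removed
      occ <- raw_occupancy(dd$reads, sim$template,
                           sprintf("%s_rep%d", cond, r), cond)
      normalize_track(occ)
    })
  })
  attr(out, "dedup_removed") <- removed
  out
}
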