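# End-to-end orchestration of the analysis stages on a (synthetic or
# user-supplied) cohort, plus plain-text I/O for the interchange formats:
# newick trees, FASTA, OTU tables as TSV (samples in rows), metadata and
# trait tables as CSV.

#' Write / read an OTU count table as TSV
#'
#' Samples in rows (first column `sample_id`), OTUs in columns, integer
#' counts.
#'
#' @param counts Matrix samples x OTUs.
#' @param path File path.
#' @return `read_otu_table` returns the integer count matrix.
#' @export
write_otu_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a trait table (values + provenance) as CSV
#'
#' @param tt A [trait_table()].
#' @param path Values CSV path; provenance goes to
#'   `<path minus .csv>_provenance.csv`.
#' @export
write_trait_table <- function(tt, path) {
  utils::write.csv(data.frame(taxon = rownames(tt$values), tt$values,
                              check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  ppath <- sub("\\.csv$", "_provenance.csv", path)
  utils::write.csv(data.frame(taxon = rownames(tt$provenance),
                              tt$provenance, check.names = FALSE),
                   ppath, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a bundle of pipeline input files
#'
#' Schema checks for the interchange formats: FASTA alphabet, newick
#' parseability, OTU-table integer counts, metadata key columns, trait
#' vocabulary membership. All violations are collected (with row/line
#' context) rather than stopping at the first.
#'
#' @param paths Named list with any of `otu_table`, `metadata`, `traits`,
#'   `tree`, `fasta`.
#' @return Character vector of error messages (empty when everything is
#'   valid).
#' @export
validate_inputs <- function(paths) {
  errs <- character()
  add <- function(...) errs <<- c(errs, paste0(...))
  if (!is.null(paths$fasta)) {
    seqs <- tryCatch(read_fasta(paths$fasta), error = function(e) NULL)
    if (is.null(seqs)) add("fasta: unparseable file ", paths$fasta)
    else {
      bad <- grepl("[^ACGTN]", seqs)
      for (i in which(bad))
        add("fasta: sequence ", names(seqs)[i], " has non-ACGTN characters")
    }
  }
  if (!is.null(paths$tree)) {
    tr <- tryCatch(ape::read.tree(paths$tree), error = function(e) NULL)
    if (is.null(tr)) add("tree: unparseable newick ", paths$tree)
    else if (is.null(tr$edge.length)) add("tree: branch lengths required")
  }
  if (!is.null(paths$otu_table)) {
    m <- tryCatch(utils::read.delim(paths$otu_table, check.names = FALSE),
                  error = function(e) NULL)
    if (is.null(m)) add("otu_table: unreadable ", paths$otu_table)
    else {
      v <- as.matrix(m[, -1, drop = FALSE])
      bad <- which(!is.finite(v) | v < 0 | v != round(v), arr.ind = TRUE)
      for (r in seq_len(min(nrow(bad), 20)))
        add("otu_table: invalid count at sample ", m[[1]][bad[r, 1]],
            ", OTU ", colnames(v)[bad[r, 2]])
    }
  }
  if (!is.null(paths$metadata)) {
    md <- tryCatch(utils::read.csv(paths$metadata), error = function(e) NULL)
    if (is.null(md)) add("metadata: unreadable ", paths$metadata)
    else {
      req <- c("sample_id", "infant_id", "age_days", "delivery_mode",
               "abx_days")
      for (col in setdiff(req, names(md)))
        add("metadata: missing column ", col)
    }
  }
  if (!is.null(paths$traits)) {
    tr <- tryCatch(utils::read.csv(paths$traits), error = function(e) NULL)
    if (is.null(tr)) add("traits: unreadable ", paths$traits)
    else {
      voc <- trait_vocabulary()$trait
      cols <- if (all(c("taxon", "trait") %in% names(tr)))
        unique(tr$trait) else setdiff(names(tr), "taxon")
      for (bad in setdiff(cols, voc))
        add("traits: unknown trait name '", bad,
            "' (expected one of the 16-trait vocabulary)")
    }
  }
  errs
}

#' Run the full trait-based succession pipeline on a synthetic cohort
#'
#' One call covering every stage: simulate the cohort, infer hidden trait
#' values per trait by hidden-state prediction, fit conservatism
#' thresholds and gate the predictions, rarefy, build CWM profiles,
#' classify OTU trends, compute cohort contrasts and the six compositional
#' series (Bray-Curtis and trait-space versions of variability,
#' directional turnover and convergence), and run trait-shuffling null
#' ensembles with observed-vs-null tests. All artifacts can be written as
#' plain-text files.
#'
#' @param config A [sim_config()]; its `seed` drives every stage.
#' @param hsp_method Hidden-state prediction method of record (default
#'   `"wscp"`).
#' @param rarefy_depth Rarefaction depth; defaults to the smaller of 5000
#'   and the simulated sequencing depth.
#' @param n_null_reps Null-model replicates (default 1000; tests and
#'   examples use fewer).
#' @param output_dir Optional directory for TSV/CSV artifacts and a run
#'   manifest.
#' @param trait_linked Passed to [simulate_cohort()].
#' @return A list of class `succession_pipeline` with elements `sim`,
#'   `hsp_fits`, `conservatism`, `gated` (OTU x trait matrix),
#'   `coverage`, `rarefied`, `profile`, `classification`, `trajectory`,
#'   `cohorts`, `contrasts`, `series` (list), `null` (list of ensembles
#'   and tests).
#' @export
run_pipeline <- function(config = sim_config(), hsp_method = "wscp",
                         rarefy_depth = NULL, n_null_reps = 1000,
                         output_dir = NULL, trait_linked = TRUE) {
  if (is.null(rarefy_depth)) rarefy_depth <- min(5000L, config$depth)
  sim <- simulate_cohort(config, trait_linked = trait_linked)
  traits <- colnames(sim$trait_table$values)

  hsp_fits <- list(); cons <- list()
  gated <- matrix(NA_real_, config$n_tips, length(traits),
                  dimnames = list(sim$tree$tip.label, traits))
  coverage <- stats::setNames(numeric(length(traits)), traits)
  for (tr in traits) {
    obs <- sim$trait_table$values[, tr]
    hsp_fits[[tr]] <- hsp(sim$tree, obs, method = hsp_method)
    cons[[tr]] <- trait_conservatism(
      sim$tree, obs, trait = tr,
      seed = stage_seed(config$seed, paste0("threshold_", tr)))
    g <- gate_predictions(hsp_fits[[tr]], cons[[tr]])
    gated[, tr] <- g$values
    coverage[tr] <- g$coverage
  }

  rarefied <- rarefy(sim$dataset, depth = rarefy_depth,
                     seed = stage_seed(config$seed, "rarefy"))
  profile <- cwm_profile(rarefied, gated)
  classification <- classify_otus(rarefied)
  trajectory <- monthly_cwm_trajectory(profile)
  cohorts <- assign_cohorts(rarefied$metadata)
  contrasts <- cohort_contrast(profile, cohorts)

  bc <- bray_curtis_matrix(rarefied)
  td <- trait_distance_matrix(profile)
  series <- list(
    bray_variability = variability_series(rarefied, bc),
    bray_directional = directional_series(rarefied, bc),
    bray_convergence = convergence_series(rarefied, bc),
    trait_variability = variability_series(rarefied, td),
    trait_directional = directional_series(rarefied, td),
    trait_convergence = convergence_series(rarefied, td))

  null <- list()
  for (st in c("variability", "directional", "convergence")) {
    ens <- null_series(rarefied, gated, st, n_reps = n_null_reps,
                       seed = stage_seed(config$seed, paste0("null_", st)))
    null[[st]] <- list(ensemble = ens, test = observed_vs_null_test(ens))
  }

  out <- structure(list(sim = sim, hsp_fits = hsp_fits,
                        conservatism = cons, gated = gated,
                        coverage = coverage, rarefied = rarefied,
                        profile = profile, classification = classification,
                        trajectory = trajectory, cohorts = cohorts,
                        contrasts = contrasts, series = series, null = null,
                        config = config),
                   class = "succession_pipeline")
  if (!is.null(output_dir)) write_pipeline_artifacts(out, output_dir)
  out
}

#' @export
print.succession_pipeline <- function(x, ...) {
  cat("Trait-based succession pipeline\n")
  cat("  pool:", x$config$n_tips, "OTUs;",
      x$config$n_infants, "infants over", x$config$months, "months\n")
  th <- vapply(x$conservatism, `[[`, numeric(1), "threshold")
  cat("  conservatism thresholds:\n")
  for (tr in names(th))
    cat(sprintf("    %-22s best=%-10s threshold=%.3f coverage=%.2f\n", tr,
                x$conservatism[[tr]]$best_model, th[tr], x$coverage[tr]))
  cat("  OTU classes:",
      paste(names(table(x$classification$class)),
            table(x$classification$class), collapse = ", "), "\n")
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Emits the newick tree, OTU tables (raw and rarefied), metadata CSV,
#' gated trait CSV, per-trait threshold table (trait, best model,
#' parameters, null expectation, max distance), classification, CWM
#' trajectory, contrasts, the six series, null-model test tables, and a
#' `manifest.txt` echoing the full resolved configuration.
#'
#' @param pipeline A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @export
write_pipeline_artifacts <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  ape::write.tree(pipeline$sim$tree, p("tree.nwk"))
  write_otu_table(pipeline$sim$dataset$counts, p("otu_table.tsv"))
  write_otu_table(pipeline$rarefied$counts, p("otu_table_rarefied.tsv"))
  utils::write.csv(pipeline$rarefied$metadata, p("metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(taxon = rownames(pipeline$gated),
                              pipeline$gated, check.names = FALSE),
                   p("traits_gated.csv"), row.names = FALSE)
  th <- do.call(rbind, lapply(names(pipeline$conservatism), function(tr) {
    cf <- pipeline$conservatism[[tr]]
    co <- cf$fits[[cf$best_model]]$coef
    data.frame(trait = tr, best_model = cf$best_model,
               a = if ("a" %in% names(co)) co[["a"]] else NA,
               b = if ("b" %in% names(co)) co[["b"]] else NA,
               c = if ("c" %in% names(co)) co[["c"]] else NA,
               null_expectation = cf$null_expectation,
               max_distance = cf$threshold,
               coverage = pipeline$coverage[[tr]])
  }))
  utils::write.csv(th, p("thresholds.csv"), row.names = FALSE)
  utils::write.csv(pipeline$classification, p("classification.csv"),
                   row.names = FALSE)
  utils::write.csv(pipeline$trajectory, p("cwm_trajectory.csv"),
                   row.names = FALSE)
  utils::write.csv(pipeline$contrasts, p("cohort_contrasts.csv"),
                   row.names = FALSE)
  ser <- do.call(rbind, lapply(names(pipeline$series), function(nm)
    cbind(measure = nm, pipeline$series[[nm]]$summary)))
  utils::write.csv(ser, p("series.csv"), row.names = FALSE)
  nt <- do.call(rbind, lapply(names(pipeline$null), function(nm)
    cbind(statistic = nm, pipeline$null[[nm]]$test)))
  utils::write.csv(nt, p("null_tests.csv"), row.names = FALSE)
  cfg <- pipeline$config
  writeLines(c("traitsuccession run manifest",
               paste0(names(cfg)[names(cfg) != "cohort_effects"], " = ",
                      vapply(cfg[names(cfg) != "cohort_effects"],
                             function(v) paste(format(v), collapse = ","),
                             character(1))),
               paste0("cohort_effects = ",
                      length(cfg$cohort_effects), " effects")),
             p("manifest.txt"))
  invisible(dir)
}
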