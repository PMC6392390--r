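# End-to-end orchestration: filter -> concatenate -> distances -> best-close
# match -> gap/discrimination -> concordance -> trees -> monophyly, with all
# artifacts written to an output directory and listed in a hashed manifest.

#' Pipeline configuration
#'
#' @param loci loci to analyse individually (default: all in the dataset).
#' @param include_concatenated also analyse the concatenation of `loci`
#'   (default TRUE when more than one locus).
#' @param model,gamma_shape distance model (see
#'   [distance_model_params()]).
#' @param min_representatives species-representative filter for the
#'   distance-based analyses (default 2).
#' @param bcm a [bcm_config()].
#' @param bin_width histogram bin width (default 0.01).
#' @param support_min,require_support monophyly support criterion (default
#'   strict > 70).
#' @param bootstrap_replicates NJ bootstrap replicates (default 1000).
#' @param run_parsimony also build an MP tree by NNI search from the NJ
#'   tree and score monophyly on it (default TRUE).
#' @param exclude_flagged drop specimens whose concordance category is
#'   `incorrect` or `mislabeled` before the distance-based analyses
#'   (default TRUE), mirroring the practice of removing presumably
#'   mislabeled barcodes from identification tests.
#' @param seed integer seed for the bootstrap resampling.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(loci = NULL, include_concatenated = TRUE,
                            model = "tn93", gamma_shape = NULL,
                            min_representatives = 2, bcm = bcm_config(),
                            bin_width = 0.01, support_min = 70,
                            require_support = TRUE,
                            bootstrap_replicates = 1000,
                            run_parsimony = TRUE, exclude_flagged = TRUE,
                            seed = 1) {
  structure(list(loci = loci, include_concatenated = include_concatenated,
                 params = distance_model_params(model, gamma_shape),
                 min_representatives = min_representatives, bcm = bcm,
                 bin_width = bin_width, support_min = support_min,
                 require_support = require_support,
                 bootstrap_replicates = bootstrap_replicates,
                 run_parsimony = run_parsimony,
                 exclude_flagged = exclude_flagged, seed = seed),
            class = "pipeline_config")
}

#' Restrict a dataset to a set of specimen ids
#'
#' Keeps the named specimens in the metadata and in every alignment
#' (original order preserved); alignments left with no members are
#' dropped.
#'
#' @param ds a [multilocus_dataset()].
#' @param ids specimen ids to keep.
#' @return the restricted [multilocus_dataset()].
#' @export
subset_dataset <- function(ds, ids) {
  specimens <- ds$specimens[ds$specimens$specimen_id %in% ids, ,
                            drop = FALSE]
  rownames(specimens) <- NULL
  alignments <- list()
  for (locus in names(ds$alignments)) {
    aln <- ds$alignments[[locus]]
    keep <- aln$ids[aln$ids %in% specimens$specimen_id]
    if (length(keep))
      alignments[[locus]] <- locus_alignment(locus, aln$seqs[keep],
                                             boundaries = aln$boundaries)
  }
  structure(list(specimens = specimens, alignments = alignments),
            class = "multilocus_dataset")
}

# deterministic JSON writer for report fragments
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE, na = "null")
  path
}

#' Run the full barcode-effectiveness pipeline
#'
#' For every configured locus and (optionally) their concatenation:
#' restricts the cohort to species with enough representatives, computes
#' the divergence matrix, the intra/inter partition with the Welch test,
#' the barcoding-gap report and histogram, per-species discrimination, the
#' best-close-match test, the bootstrapped NJ tree (plus an MP tree by NNI
#' search) and monophyly percentages at species/genus/family rank. The
#' morphology-vs-molecular concordance summary is computed over the whole
#' dataset. All artifacts are written under `out_dir` and listed in
#' `manifest.tsv` with MD5 content hashes: identical input, configuration
#' and seed yield an identical manifest.
#'
#' @param ds a [multilocus_dataset()].
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `report` (nested list of per-analysis
#'   results), `manifest` (data.frame `file`, `md5`) and `out_dir`.
#' @export
run_pipeline <- function(ds, cfg = pipeline_config(), out_dir) {
  stopifnot(inherits(ds, "multilocus_dataset"),
            inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  loci <- if (is.null(cfg$loci)) names(ds$alignments) else cfg$loci
  miss <- setdiff(loci, names(ds$alignments))
  if (length(miss)) stop("configured locus '", miss[1L],
                         "' is not in the dataset")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_line <- function(...) message("[barcodeval] ", ...)

  # concordance first: flagged (incorrect/mislabeled) specimens can be
  # excluded from the identification analyses, as is standard practice
  conc_records <- tryCatch(dataset_concordance(ds), error = function(e) {
    log_line("concordance skipped: ", conditionMessage(e))
    NULL
  })
  ds_use <- ds
  if (!is.null(conc_records) && cfg$exclude_flagged) {
    flagged <- conc_records$specimen_id[
      conc_records$category %in% c("incorrect", "mislabeled")]
    if (length(flagged)) {
      log_line("excluding ", length(flagged),
               " flagged specimen(s) from distance analyses")
      ds_use <- subset_dataset(ds, setdiff(ds$specimens$specimen_id,
                                           flagged))
    }
  }

  filtered <- stage("filter",
                    filter_min_representatives(ds_use,
                                               cfg$min_representatives))
  labels <- filtered$specimens

  analyses <- list()
  for (locus in loci) {
    aln <- stage(paste0("subset:", locus), subset_alignment(
      ds_use$alignments[[locus]], filtered$specimens$specimen_id))
    analyses[[locus]] <- aln
  }
  if (cfg$include_concatenated && length(loci) > 1L)
    analyses[[paste(loci, collapse = "+")]] <-
      stage("concatenate", concatenate_loci(filtered, loci))

  report <- list(analyses = list())
  files <- character(0)
  emit <- function(path) files[length(files) + 1L] <<- path

  for (name in names(analyses)) {
    aln <- analyses[[name]]
    tag <- gsub("[^A-Za-z0-9_.-]", "_", name)
    log_line("analysing ", name, " (", length(aln$ids), " sequences x ",
             aln$length, " columns)")
    # keep only specimens whose species still has enough representatives
    # within this alignment (dropout may have removed partners)
    sp <- species_labels(filtered)[aln$ids]
    tab <- table(sp)
    keep <- aln$ids[sp %in% names(tab)[tab >= cfg$min_representatives]]
    aln <- stage(paste0("cohort:", name), subset_alignment(aln, keep))

    m <- stage(paste0("distances:", name), distance_matrix(aln,
                                                           cfg$params))
    emit(write_distance_matrix(m, file.path(out_dir,
                                            paste0(tag, "_distances.tsv"))))
    part <- stage(paste0("partition:", name),
                  partition_divergences(m, labels))
    welch <- stage(paste0("welch:", name),
                   welch_t_test(part$intra$distance, part$inter$distance))
    gap <- stage(paste0("gap:", name), barcoding_gap_test(part))
    hist <- stage(paste0("histogram:", name),
                  divergence_histogram(part, cfg$bin_width))
    hp <- file.path(out_dir, paste0(tag, "_histogram.tsv"))
    utils::write.table(hist, hp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(hp)
    disc <- stage(paste0("discrimination:", name),
                  species_discrimination(m, labels))
    dp <- file.path(out_dir, paste0(tag, "_discrimination.tsv"))
    utils::write.table(disc$per_species, dp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(dp)
    bcm <- stage(paste0("bcm:", name),
                 best_close_match(m, labels, cfg$bcm))
    bp <- file.path(out_dir, paste0(tag, "_bcm.tsv"))
    utils::write.table(bcm$records, bp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(bp)

    nj <- stage(paste0("bootstrap:", name),
                bootstrap_support(aln, cfg$params,
                                  cfg$bootstrap_replicates,
                                  seed = derive_seed(cfg$seed,
                                                     paste0("boot:", name))))
    emit(write_tree_newick(nj, file.path(out_dir,
                                         paste0(tag, "_nj.nwk"))))
    mono <- list()
    for (rk in c("species", "genus", "family"))
      mono[[rk]] <- stage(paste0("monophyly:", name, ":", rk),
                          monophyly_percent(nj, labels, rank = rk,
                                            support_min = cfg$support_min,
                                            require_support =
                                              cfg$require_support))
    mono_mp <- NULL
    if (cfg$run_parsimony) {
      mp <- stage(paste0("parsimony:", name),
                  parsimony_search(aln, start = ape::unroot(nj),
                                   lookahead = FALSE))
      emit(write_tree_newick(mp, file.path(out_dir,
                                           paste0(tag, "_mp.nwk"))))
      mono_mp <- list()
      for (rk in c("species", "genus", "family"))
        mono_mp[[rk]] <- stage(
          paste0("monophyly_mp:", name, ":", rk),
          monophyly_percent(mp, labels, rank = rk,
                            support_min = cfg$support_min,
                            require_support = FALSE))
    }
    report$analyses[[name]] <- list(
      n_sequences = length(aln$ids), n_columns = aln$length,
      welch = welch,
      gap = list(max_intra = gap$max_intra, min_inter = gap$min_inter,
                 gap_present = gap$gap_present,
                 mean_intra = gap$mean_intra,
                 mean_inter = gap$mean_inter),
      discrimination = list(n_species = disc$n_species,
                            n_discriminated = disc$n_discriminated,
                            percent = disc$percent),
      bcm = list(threshold = bcm$summary$threshold,
                 n_queries = bcm$summary$n_queries,
                 counts = as.list(bcm$summary$counts),
                 percent = as.list(bcm$summary$percent)),
      monophyly_nj = lapply(mono, function(r)
        list(percent = r$percent, n_assessable = r$n_assessable)),
      monophyly_mp = if (is.null(mono_mp)) NULL else
        lapply(mono_mp, function(r)
          list(percent = r$percent, n_assessable = r$n_assessable)))
  }

  conc <- NULL
  if (!is.null(conc_records)) {
    cp <- file.path(out_dir, "concordance.tsv")
    utils::write.table(conc_records, cp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(cp)
    s <- summarize_concordance(conc_records)
    conc <- list(counts = as.list(s$counts), percent = as.list(s$percent),
                 n_assessed = s$n_assessed,
                 n_unassessed = s$n_unassessed)
  }
  report$concordance <- conc

  emit(write_report_json(report, file.path(out_dir, "report.json")))
  md <- render_report_md(report)
  mdp <- file.path(out_dir, "report.md")
  writeLines(md, mdp)
  emit(mdp)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(report = report, manifest = manifest,
                 out_dir = out_dir))
}

# markdown summary: one table per statistic, loci as rows; the monophyly
# table follows the classic rank x method layout
render_report_md <- function(report) {
  lines <- c("# Barcode effectiveness report", "")
  lines <- c(lines, "## Identification success (best-close match)", "",
             "| Barcode | T | Correct % | Ambiguous % | Incorrect % | Unidentified % |",
             "|---|---|---|---|---|---|")
  for (name in names(report$analyses)) {
    a <- report$analyses[[name]]
    lines <- c(lines, sprintf(
      "| %s | %.5g | %.1f | %.1f | %.1f | %.1f |", name,
      a$bcm$threshold, a$bcm$percent$correct, a$bcm$percent$ambiguous,
      a$bcm$percent$incorrect, a$bcm$percent$unidentified))
  }
  lines <- c(lines, "", "## Divergences and barcoding gap", "",
             "| Barcode | Mean intra | Mean inter | Welch p | Gap present | Discrimination % |",
             "|---|---|---|---|---|---|")
  for (name in names(report$analyses)) {
    a <- report$analyses[[name]]
    lines <- c(lines, sprintf(
      "| %s | %.5g | %.5g | %.3g | %s | %.1f |", name, a$gap$mean_intra,
      a$gap$mean_inter, a$welch$p_value,
      if (a$gap$gap_present) "yes" else "no",
      a$discrimination$percent))
  }
  lines <- c(lines, "", "## Monophyletic clades (support-filtered NJ / MP)",
             "",
             "| Barcode | Method | Family % | Genus % | Species % |",
             "|---|---|---|---|---|")
  for (name in names(report$analyses)) {
    a <- report$analyses[[name]]
    lines <- c(lines, sprintf(
      "| %s | NJ | %.1f | %.1f | %.1f |", name,
      a$monophyly_nj$family$percent, a$monophyly_nj$genus$percent,
      a$monophyly_nj$species$percent))
    if (!is.null(a$monophyly_mp))
      lines <- c(lines, sprintf(
        "| %s | MP | %.1f | %.1f | %.1f |", name,
        a$monophyly_mp$family$percent, a$monophyly_mp$genus$percent,
        a$monophyly_mp$species$percent))
  }
  if (!is.null(report$concordance)) {
    lines <- c(lines, "", "## Morphology vs molecular concordance", "",
               "| Category | Count | Percent |", "|---|---|---|")
    for (k in names(report$concordance$counts))
      lines <- c(lines, sprintf("| %s | %d | %.1f |", k,
                                report$concordance$counts[[k]],
                                report$concordance$percent[[k]]))
  }
  lines
}
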