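# Orchestration and reporting: stage sequencing over a run configuration,
# TSV report writers mirroring the supplementary-table layouts, the
# structural -log10(p) -> RGB color mapping, and a run manifest.

#' Map association strengths to structure colors
#'
#' Linearly normalizes -log10(p) values to [0, 1] and maps each position to
#' the RGB triple (x, 0, 1 - x): the most associated position is deep red
#' (1, 0, 0), the least associated deep blue (0, 0, 1).
#'
#' @param neglog_p Numeric vector (>= 2 finite values).
#' @return data.frame: value, r, g, b.
#' @export
color_map <- function(neglog_p) {
  stopifnot(length(neglog_p) >= 2, all(is.finite(neglog_p)))
  rng <- range(neglog_p)
  if (rng[1] == rng[2]) {
    warning("all values equal; mapping everything to (0,0,1)")
    x <- rep(0, length(neglog_p))
  } else {
    x <- (neglog_p - rng[1]) / (rng[2] - rng[1])
  }
  data.frame(value = neglog_p, r = x, g = 0, b = 1 - x)
}

#' Write a structure-coloring script
#'
#' Plain-text "position -> RGB" lines consumable by a molecular viewer.
#'
#' @param positions Position labels.
#' @param colors \code{\link{color_map}} output.
#' @param path Output path.
#' @export
write_color_script <- function(positions, colors, path) {
  stopifnot(length(positions) == nrow(colors))
  writeLines(sprintf("%s\t%.4f\t%.4f\t%.4f", positions,
                     colors$r, colors$g, colors$b), path)
  invisible(path)
}

write_tsv <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run configuration for the full pipeline
#'
#' @param sim A \code{sim_config} for the synthetic cohort (or NULL when
#'   dosage/panel paths are given).
#' @param stages Character vector of enabled stages, a subset of
#'   \code{c("filter", "scan", "meta", "burden", "heritability",
#'   "haplotypes", "subpheno", "epitope", "report")}.
#' @param alpha_gws,alpha_omnibus,r2_min,r2_min_eqtl,certainty_min,K
#'   Analysis thresholds (defaults: 5e-8, 5e-5, 0.7, 0.8, 0.8, 0.001).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(sim = NULL, stages = c("filter", "scan", "burden",
                                              "heritability", "haplotypes",
                                              "subpheno", "epitope", "report"),
                       alpha_gws = 5e-8, alpha_omnibus = 5e-5, r2_min = 0.7,
                       r2_min_eqtl = 0.8, certainty_min = 0.8, K = 0.001,
                       seed = 1L, out_dir = "results") {
  stopifnot(alpha_gws > 0, alpha_gws < 1, alpha_omnibus > 0, alpha_omnibus < 1,
            r2_min >= 0, r2_min <= 1, certainty_min > 0.5, certainty_min <= 1,
            K > 0, K < 1)
  structure(list(sim = sim, stages = stages, alpha_gws = alpha_gws,
                 alpha_omnibus = alpha_omnibus, r2_min = r2_min,
                 r2_min_eqtl = r2_min_eqtl, certainty_min = certainty_min,
                 K = K, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Execute the enabled pipeline stages in order
#'
#' filter -> scan -> burden -> heritability -> haplotypes -> subpheno ->
#' epitope -> report, deterministically given the seed, writing per-stage
#' TSVs plus a JSON manifest (stage list, outputs, seed, config hash). A
#' stage failure aborts with the stage name; outputs of completed stages
#' are preserved.
#'
#' @param config A \code{run_config} whose \code{sim} drives the cohort.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"), !is.null(config$sim))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_file <- file.path(tempdir(), "run_config.json")
  jsonlite::write_json(config[setdiff(names(config), c("sim", "out_dir"))],
                       cfg_file, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(cfg_file))
  manifest <- list(seed = config$seed, config_hash = hash,
                   stages = character(0), outputs = character(0))
  results <- list()
  emit <- function(stage, name, df) {
    path <- file.path(config$out_dir, name)
    write_tsv(df, path, config_hash = hash)
    manifest$outputs <<- c(manifest$outputs, path)
  }
  stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages <<- c(manifest$stages, name)
    results[[name]] <<- res
    res
  }

  sim <- simulate_cohort(config$sim)
  dm <- sim$dosage
  panel <- sim$panel

  dm_f <- stage("filter", function() {
    out <- filter_markers(dm, r2_min = config$r2_min)
    emit("filter", "markers_filtered.tsv",
         data.frame(marker = out$markers$id, r2 = out$markers$r2))
    out
  })
  if (is.null(dm_f)) dm_f <- dm

  scan <- stage("scan", function() {
    sc <- stepwise_scan(dm_f, panel, alpha_omnibus = config$alpha_omnibus)
    emit("scan", "conditional_ledger.tsv", sc$ledger)
    emit("scan", "independent_positions.tsv", sc$selected)
    sc
  })

  stage("burden", function() {
    if (is.null(scan) || !nrow(scan$selected)) return(NULL)
    ids <- risk_residue_ids(config$sim, scan$selected)
    ids <- intersect(ids, colnames(dm_f$dosage))
    if (length(ids) < 2) return(NULL)
    calls <- hard_call(dm_f$dosage[, ids, drop = FALSE],
                       certainty_min = config$certainty_min)
    bt <- burden_analysis(calls, panel, auc = FALSE)
    emit("burden", "burden_bins.tsv", bt$bins)
    bt
  })

  stage("heritability", function() {
    if (is.null(config$sim$causal_effects)) return(NULL)
    ce <- config$sim$causal_effects
    ids <- mapply(aa_marker_id, ce$gene, ce$aa_pos, ce$residue)
    ok <- ids %in% colnames(dm_f$dosage)
    res <- data.frame(name = paste0(ce$gene, "-", ce$aa_pos, ce$residue)[ok],
                      raf = colMeans(dm_f$dosage[, ids[ok], drop = FALSE]) / 2,
                      or = exp(ce$beta[ok]))
    h <- total_heritability(res, K = config$K)
    emit("heritability", "heritability.tsv",
         data.frame(h$table, percent_total = h$percent))
    h
  })

  stage("haplotypes", function() {
    if (is.null(scan) || nrow(scan$selected) < 2) return(NULL)
    ids <- risk_residue_ids(config$sim, scan$selected)[1:2]
    ids <- intersect(ids, colnames(dm_f$dosage))
    if (length(ids) < 2) return(NULL)
    calls <- hard_call(dm_f$dosage[, ids, drop = FALSE],
                       certainty_min = config$certainty_min)
    ht <- em_haplotypes(genotype_from_calls(calls), seed = config$seed)
    ha <- haplotype_assoc(ht, panel)
    emit("haplotypes", "haplotype_assoc.tsv", ha)
    list(table = ht, assoc = ha)
  })

  stage("subpheno", function() {
    abs_ <- panel_antibodies(panel)
    out <- list()
    for (ab in abs_) {
      res <- tryCatch(subphenotype_contrasts(dm_f, panel, ab, markers = FALSE),
                      error = function(e) NULL)
      if (is.null(res)) next
      emit("subpheno", paste0("subpheno_", ab, "_case_only.tsv"),
           res$case_only$omnibus)
      out[[ab]] <- res
    }
    out
  })

  stage("epitope", function() {
    pot <- load_contact_potential()
    sle <- classify(preference_scores(pot, residue_lists("SLE")))
    ra <- classify(preference_scores(pot, residue_lists("RA")))
    emit("epitope", "preference_scores_sle.tsv", sle)
    emit("epitope", "preference_scores_ra.tsv", ra)
    list(SLE = sle, RA = ra)
  })

  stage("report", function() {
    if (is.null(scan) || is.null(scan$ledger) || !nrow(scan$ledger))
      return(NULL)
    first <- scan$ledger[scan$ledger$step == 1 & scan$ledger$stage == "scan", ]
    nl <- -log10(pmax(first$p, .Machine$double.xmin))
    cm <- color_map(nl)
    pos_lab <- paste0(first$gene, "_", first$aa_pos)
    write_color_script(pos_lab, cm,
                       file.path(config$out_dir, "position_colors.txt"))
    manifest$outputs <<- c(manifest$outputs,
                           file.path(config$out_dir, "position_colors.txt"))
    cm
  })

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(list(results = results, manifest = manifest, sim = sim))
}

# Marker ids of the planted risk residues, in scan-selection order where
# possible (falls back to the configured causal effects).
risk_residue_ids <- function(sim_cfg, selected) {
  ce <- sim_cfg$causal_effects
  if (is.null(ce)) return(character(0))
  ord <- order(match(paste0(ce$gene, "_", ce$aa_pos),
                     paste0(selected$gene, "_", selected$aa_pos)))
  mapply(aa_marker_id, ce$gene[ord], ce$aa_pos[ord], ce$residue[ord])
}
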