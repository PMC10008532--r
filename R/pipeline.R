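write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_stage(stage, conditionMessage(e)))
}

#' Run the full spike-in analysis pipeline
#'
#' Executes detect -> qc -> quantify -> transform -> diversity on either
#' a simulated experiment or user-supplied files, and writes all result
#' tables (TSV), a YAML QC summary, optional figures (PDF) and a plain
#' text log into the output directory. Given the same config and seed
#' the result tables are byte-identical across runs.
#'
#' Recognised config fields (a nested list, or the path to a YAML file
#' for [read_config()]):
#' \describe{
#'   \item{`simulate`}{arguments for [simulation_config()] (e.g.
#'     `n_replicates`, `depth`); mutually exclusive with `inputs`.}
#'   \item{`inputs`}{paths: `counts` (+ optional `counts_format`,
#'     `counts_orientation`), `metadata`, `sequences`,
#'     `mc_reference_fasta` (FASTA named by taxon, or the string
#'     `"example"` for the packaged synthetic pair). Optional
#'     `copies_per_dose` / `cells_per_dose` named lists override the
#'     default dose constants.}
#'   \item{`detect`}{`min_identity` (default 97).}
#'   \item{`qc`}{`band` (default `c(0.01, 0.10)`).}
#'   \item{`transform`}{logical; rescale counts to absolute copy scale
#'     (default `TRUE` when any sample is dosed).}
#'   \item{`diversity`}{`terms` (default `pool_id` then
#'     `mc_biomass_ratio` where available), `n_perm` (default 999).}
#'   \item{`output`}{output directory.}
#'   \item{`seed`}{default seed for all randomized stages.}
#'   \item{`figures`}{logical, write PDF figures (default `TRUE`).}
#' }
#'
#' @param config list or YAML path.
#' @param seed overrides `config$seed`.
#' @param outdir overrides `config$output`.
#' @return (invisibly) a list with all intermediate objects and the
#'   paths of the written files.
#' @export
run_pipeline <- function(config, seed = NULL, outdir = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(is.list(config))
  seed <- seed %||% config$seed %||% 1L
  outdir <- outdir %||% config$output
  if (is.null(outdir))
    stop_stage("config", "no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("spikeline pipeline", sprintf("seed: %s", format(seed)))
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv(df, p)
    files[[name]] <<- p
    log_lines <<- c(log_lines, sprintf("wrote %s", name))
  }

  # ---- stage: inputs -------------------------------------------------
  sim <- NULL
  if (!is.null(config$simulate)) {
    sim <- run_stage("simulate", {
      args <- config$simulate
      if (!is.null(args$n_replicates)) {
        args$design <- bovine_design(n_replicates = args$n_replicates)
        args$n_replicates <- NULL
      }
      args$seed <- args$seed %||% seed
      simulate_experiment(do.call(simulation_config, args))
    })
    table <- sim$table
    svs <- sim$sequences
    metadata <- sim$metadata
    refs <- sim$refs
    log_lines <- c(log_lines, sprintf(
      "simulated %d samples x %d SVs at depth %d",
      nrow(counts(table)), ncol(counts(table)), sim$config$depth))
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    table <- run_stage("inputs", read_count_table(
      inp$counts, format = inp$counts_format %||% "auto",
      orientation = inp$counts_orientation %||% "samples"))
    metadata <- run_stage("inputs",
                          validate_metadata(read_metadata(inp$metadata),
                                            table))
    svs <- run_stage("inputs", read_sv_sequences(inp$sequences))
    refs <- run_stage("config", {
      if (is.null(inp$mc_reference_fasta)) {
        want_transform <- isTRUE(config$transform) ||
          (is.null(config$transform) && any(metadata$mc_dose_fraction > 0))
        if (want_transform)
          stop("transformation requested but no MC reference supplied ",
               "(inputs$mc_reference_fasta)")
        NULL
      } else if (identical(inp$mc_reference_fasta, "example")) {
        example_mc_references()
      } else {
        s <- Biostrings::readDNAStringSet(inp$mc_reference_fasta)
        cpd <- unlist(inp$copies_per_dose %||%
                        list("Imtechella halotolerans" = 6.0e7,
                             "Allobacillus halotolerans" = 1.4e8))
        gram <- unlist(inp$gram %||%
                         list("Imtechella halotolerans" = "negative",
                              "Allobacillus halotolerans" = "positive"))
        taxa <- names(s)
        mc_references(taxon = taxa, gram = gram[taxa],
                      copies_per_dose = cpd[taxa],
                      cells_per_dose =
                        rep(unlist(inp$cells_per_dose %||% 2e7),
                            length.out = length(taxa)),
                      sequences = setNames(as.character(s), taxa))
      }
    })
  } else {
    stop_stage("config", "config needs either 'simulate' or 'inputs'")
  }

  # ---- stage: detect -------------------------------------------------
  assignment <- NULL
  if (!is.null(refs)) {
    assignment <- run_stage("detect", suppressWarnings(
      assign_mc_svs(svs, refs, table,
                    min_identity = config$detect$min_identity %||% 97)))
    emit(assignment$assignments, "mc_assignment.tsv")
  }

  # ---- stage: qc -----------------------------------------------------
  qc <- NULL
  if (!is.null(assignment)) {
    band <- unlist(config$qc$band %||% c(0.01, 0.10))
    qc <- run_stage("qc", mc_qc(table, assignment, refs, band = band,
                                metadata = metadata))
    emit(qc$per_sample, "mc_qc.tsv")
    p <- file.path(outdir, "mc_qc_summary.yaml")
    yaml::write_yaml(qc$summary, p)
    files[["mc_qc_summary.yaml"]] <- p
  }

  # ---- stage: quantify + transform ----------------------------------
  gcn <- transformed <- stripped <- NULL
  if (!is.null(assignment)) {
    gcn <- run_stage("quantify", suppressWarnings(
      estimate_gcn(table, assignment, metadata, refs)))
    emit(gcn, "gcn_estimates.tsv")
    grouping <- interaction(metadata$pool_id, metadata$condition,
                            drop = TRUE)
    out_flags <- run_stage("quantify", suppressWarnings(
      flag_outliers(gcn, setNames(as.character(grouping),
                                  metadata$sample_id))))
    emit(out_flags, "outlier_flags.tsv")
    est <- gcn$gcn[!is.na(gcn$gcn)]
    if (length(est)) {
      rec <- run_stage("quantify", recommend_dose(
        median(est), refs, band = unlist(config$qc$band %||% c(0.01, 0.10))))
      p <- file.path(outdir, "dose_recommendation.yaml")
      yaml::write_yaml(as.list(rec), p)
      files[["dose_recommendation.yaml"]] <- p
    }
    stripped <- run_stage("transform", strip_mc(table, assignment))
    want_transform <- config$transform %||% any(!is.na(gcn$gcn))
    if (isTRUE(want_transform)) {
      transformed <- run_stage("transform", suppressWarnings(
        transform_counts(stripped, gcn)))
      emit(data.frame(sample_id = rownames(transformed),
                      as.data.frame(unclass(transformed)),
                      check.names = FALSE),
           "transformed_counts.tsv")
    }
  } else {
    stripped <- table
  }

  # ---- stage: diversity ---------------------------------------------
  div <- run_stage("diversity", {
    clr <- clr_normalize(stripped)
    d_eucl <- distance_matrix(clr, "euclidean")
    rar <- suppressWarnings(rarefy_table(stripped, seed = seed))
    d_bray <- distance_matrix(rar, "bray_curtis")
    alpha <- alpha_diversity(rar)
    pc_e <- pcoa(d_eucl)
    pc_b <- pcoa(d_bray)
    terms <- config$diversity$terms
    md <- metadata
    md$mc_biomass_ratio <- unname(mc_biomass_ratio(metadata))
    if (is.null(terms)) {
      terms <- character(0)
      if (length(unique(md$pool_id[!is.na(md$pool_id)])) > 1)
        terms <- "pool_id"
      if (length(unique(md$mc_biomass_ratio)) > 1)
        terms <- c(terms, "mc_biomass_ratio")
    }
    perm <- list()
    if (length(terms)) {
      n_perm <- config$diversity$n_perm %||% 999
      perm$euclidean <- permanova(d_eucl, md, terms, n_perm = n_perm,
                                  seed = seed)
      md_b <- md[match(rownames(as.matrix(d_bray$matrix)),
                       md$sample_id), , drop = FALSE]
      perm$bray_curtis <- permanova(d_bray, md_b, terms,
                                    n_perm = n_perm, seed = seed)
    }
    alpha_cmp <- NULL
    if (sum(md$no_mc) >= 2 && sum(!md$no_mc) >= 2) {
      grp <- ifelse(md$no_mc, "no_mc", "mc")
      names(grp) <- md$sample_id
      alpha_cmp <- compare_alpha(alpha, grp)
    }
    list(alpha = alpha, d_eucl = d_eucl, d_bray = d_bray,
         pcoa_euclidean = pc_e, pcoa_bray = pc_b,
         permanova = perm, alpha_comparison = alpha_cmp)
  })
  emit(div$alpha, "alpha_diversity.tsv")
  emit(data.frame(sample_id = rownames(div$d_eucl$matrix),
                  div$d_eucl$matrix, check.names = FALSE),
       "distance_euclidean_clr.tsv")
  emit(data.frame(sample_id = rownames(div$d_bray$matrix),
                  div$d_bray$matrix, check.names = FALSE),
       "distance_bray_curtis.tsv")
  emit(data.frame(sample_id = rownames(div$pcoa_euclidean$coordinates),
                  div$pcoa_euclidean$coordinates, check.names = FALSE),
       "pcoa_euclidean_clr.tsv")
  for (nm in names(div$permanova))
    emit(as.data.frame(div$permanova[[nm]]),
         paste0("permanova_", nm, ".tsv"))
  if (!is.null(div$alpha_comparison))
    emit(div$alpha_comparison, "alpha_mc_vs_nomc.tsv")

  # ---- figures -------------------------------------------------------
  if (isTRUE(config$figures %||% TRUE)) {
    grDevices::pdf(file.path(outdir, "figures.pdf"), width = 7,
                   height = 6)
    on.exit(grDevices::dev.off(), add = TRUE)
    co <- div$pcoa_euclidean$coordinates
    if (ncol(co) >= 2) {
      pool <- metadata$pool_id[match(rownames(co), metadata$sample_id)]
      graphics::plot(co[, 1], co[, 2], col = as.factor(pool), pch = 19,
                     xlab = "Axis 1", ylab = "Axis 2",
                     main = "PCoA, Euclidean on CLR")
    }
    if (!is.null(gcn) && any(!is.na(gcn$log2_gcn))) {
      ok <- !is.na(gcn$log2_gcn)
      cond <- metadata$condition[match(gcn$sample_id, metadata$sample_id)]
      graphics::stripchart(gcn$log2_gcn[ok] ~ as.factor(cond[ok]),
                           vertical = TRUE, pch = 19, method = "jitter",
                           ylab = "log2 16S gene copies",
                           main = "Estimated copies per library")
    }
  }

  writeLines(log_lines, file.path(outdir, "pipeline_log.txt"))
  invisible(list(table = table, metadata = metadata, refs = refs,
                 assignment = assignment, qc = qc, gcn = gcn,
                 stripped = stripped, transformed = transformed,
                 diversity = div, files = files, sim = sim,
                 outdir = outdir))
}
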