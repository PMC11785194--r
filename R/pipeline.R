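#' Build a pipeline configuration
#'
#' A declarative description of a full run: which stages to execute
#' (`simulate`, `apms`, `harmonize`, `network`, `integrate`), the parameter
#' block of each stage, input/output paths and the single global seed from
#' which every stage's RNG seed is derived by a fixed counter scheme (so
#' adding or skipping a stage never reshuffles another stage's randomness).
#'
#' @param outdir artifact directory (created if needed).
#' @param seed global seed (integer).
#' @param stages character vector of stages to run, in pipeline order.
#' @param simulate list with optional `apms` / `cohort` sublists of
#'   [apms_sim_spec()] / [cohort_sim_spec()] arguments.
#' @param apms list: optional `input_matrix` / `input_design` TSV paths
#'   (default: the simulated AP-MS dataset in `outdir`), `imputation` and
#'   `dea` argument lists, `contrast` (bait, control).
#' @param harmonize list: optional input paths, `tampor` and `regress`
#'   argument lists.
#' @param network list: optional `params` argument list ([network_params()]),
#'   `traits` columns for the module-trait table.
#' @param integrate list: optional named `lists` of identifier-list file
#'   paths (default: the bait-enriched hits from the apms stage), optional
#'   `gmt` path, `min_set`/`max_set`.
#' @return a validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(outdir, seed = 1,
                            stages = c("simulate", "apms", "harmonize",
                                       "network", "integrate"),
                            simulate = list(), apms = list(),
                            harmonize = list(), network = list(),
                            integrate = list()) {
  known <- c("simulate", "apms", "harmonize", "network", "integrate")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg <- structure(list(outdir = outdir, seed = as.integer(seed),
                        stages = stages, simulate = simulate, apms = apms,
                        harmonize = harmonize, network = network,
                        integrate = integrate),
                   class = "PipelineConfig")
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file with the fields above.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

validate_pipeline_config <- function(cfg) {
  # pre-flight: every referenced input path must exist before any computation
  for (stage in c("apms", "harmonize")) {
    blk <- cfg[[stage]]
    for (fld in c("input_matrix", "input_design")) {
      if (!is.null(blk[[fld]]) && !file.exists(blk[[fld]]))
        stop("config ", stage, "$", fld, ": file not found: ", blk[[fld]])
      if (is.null(blk[[fld]]) && stage %in% cfg$stages &&
          !"simulate" %in% cfg$stages)
        stop("stage ", dQuote(stage), " needs ", fld,
             " when the simulate stage is not run")
    }
  }
  for (lp in cfg$integrate$lists) {
    if (!file.exists(lp)) stop("config integrate$lists: file not found: ", lp)
  }
  if (!is.null(cfg$integrate$gmt) && !file.exists(cfg$integrate$gmt))
    stop("config integrate$gmt: file not found: ", cfg$integrate$gmt)
  invisible(cfg)
}

# Counter-based seed fan-out: one fixed offset per stage, all below 2^31.
stage_seed <- function(global_seed, stage) {
  offset <- c(simulate = 101L, apms = 211L, harmonize = 307L,
              network = 401L, integrate = 503L)[[stage]]
  (as.integer(global_seed) %% 1000000L) * 1000L + offset
}

#' Run the pipeline
#'
#' Executes the requested stages in order (simulate, apms, harmonize,
#' network, integrate), writing every intermediate table to the artifact
#' directory together with a JSON manifest (parameters, derived seeds, file
#' checksums and row counts per stage) and a human-readable log. On a stage
#' failure the partial outputs are retained and the manifest records the
#' failure point before the error propagates.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @return the artifact directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  validate_pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "pipeline.log")
  logf <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ..., "\n",
        sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  manifest <- list(package = "proxinet",
                   seed = config$seed,
                   stages_requested = config$stages,
                   parameters = config[c("simulate", "apms", "harmonize",
                                         "network", "integrate")],
                   stages = list(), status = "running")
  state <- new.env(parent = emptyenv())
  for (stage in intersect(c("simulate", "apms", "harmonize", "network",
                            "integrate"), config$stages)) {
    logf("stage ", stage, ": start (seed ",
         stage_seed(config$seed, stage), ")")
    res <- tryCatch(
      run_stage(stage, config, state),
      error = function(e) e)
    if (inherits(res, "error")) {
      manifest$status <- paste0("failed at stage ", stage)
      manifest$error <- conditionMessage(res)
      write_manifest(manifest, config$outdir)
      logf("stage ", stage, ": FAILED: ", conditionMessage(res))
      stop("pipeline failed at stage ", stage, ": ",
           conditionMessage(res), call. = FALSE)
    }
    manifest$stages[[stage]] <- res
    logf("stage ", stage, ": done")
  }
  manifest$status <- "complete"
  write_manifest(manifest, config$outdir)
  logf("pipeline complete")
  invisible(config$outdir)
}

write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
}

file_entry <- function(path, n_rows = NA) {
  list(file = basename(path), md5 = unname(tools::md5sum(path)),
       n_rows = n_rows)
}

run_stage <- function(stage, config, state) {
  out <- config$outdir
  switch(stage,
    simulate = {
      sd <- stage_seed(config$seed, "simulate")
      ap_args <- config$simulate$apms
      ap_args$seed <- sd
      apms <- generate_apms(do.call(apms_sim_spec, as.list(ap_args)))
      co_args <- config$simulate$cohort
      co_args$seed <- sd + 1L
      cohort <- generate_cohort(do.call(cohort_sim_spec, as.list(co_args)))
      state$apms <- apms; state$cohort <- cohort
      f1 <- file.path(out, "apms_matrix.tsv")
      write_abundance_tsv(apms$matrix, f1)
      f2 <- file.path(out, "apms_design.tsv")
      write_design_tsv(apms$design, f2)
      f3 <- file.path(out, "apms_truth.tsv")
      utils::write.table(apms$truth, f3, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      f4 <- file.path(out, "cohort_matrix.tsv")
      write_abundance_tsv(cohort$matrix, f4)
      f5 <- file.path(out, "cohort_design.tsv")
      write_design_tsv(cohort$design, f5)
      f6 <- file.path(out, "cohort_truth_proteins.tsv")
      utils::write.table(cohort$truth$proteins, f6, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(outputs = list(file_entry(f1, nrow(apms$matrix)),
                          file_entry(f2, nrow(apms$design)),
                          file_entry(f3, nrow(apms$truth)),
                          file_entry(f4, nrow(cohort$matrix)),
                          file_entry(f5, nrow(cohort$design)),
                          file_entry(f6, nrow(cohort$truth$proteins))))
    },
    apms = {
      blk <- config$apms
      if (!is.null(blk$input_matrix)) {
        m <- read_abundance_tsv(blk$input_matrix)
        des <- read_design_tsv(blk$input_design)
      } else if (!is.null(state$apms)) {
        m <- state$apms$matrix; des <- state$apms$design
      } else {
        m <- read_abundance_tsv(file.path(out, "apms_matrix.tsv"))
        des <- read_design_tsv(file.path(out, "apms_design.tsv"))
      }
      dea_p <- do.call(dea_params, as.list(blk$dea))
      imp_args <- blk$imputation
      imp_args$seed <- stage_seed(config$seed, "apms")
      imp_p <- do.call(imputation_params, as.list(imp_args))
      filt <- filter_missingness(m, dea_p)
      imp <- impute_missing(filt, imp_p)
      dea <- run_dea(imp, des, dea_p, contrast = blk$contrast)
      dea <- classify_volcano(dea, dea_p)
      f1 <- file.path(out, "apms_dea.tsv")
      utils::write.table(dea, f1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      f2 <- file.path(out, "apms_enriched.txt")
      write_id_list(dea$protein_id[dea$class == "bait_enriched"], f2)
      f3 <- file.path(out, "apms_imputed_matrix.tsv")
      write_abundance_tsv(imp, f3)
      state$dea <- dea
      list(n_input = nrow(m), n_retained = nrow(filt),
           counts = as.list(attr(dea, "counts")),
           outputs = list(file_entry(f1, nrow(dea)),
                          file_entry(f2, sum(dea$class == "bait_enriched")),
                          file_entry(f3, nrow(imp))))
    },
    harmonize = {
      blk <- config$harmonize
      if (!is.null(blk$input_matrix)) {
        m <- read_abundance_tsv(blk$input_matrix)
        des <- read_design_tsv(blk$input_design)
      } else if (!is.null(state$cohort)) {
        m <- state$cohort$matrix; des <- state$cohort$design
      } else {
        m <- read_abundance_tsv(file.path(out, "cohort_matrix.tsv"))
        des <- read_design_tsv(file.path(out, "cohort_design.tsv"))
      }
      tp <- do.call(tampor_params, as.list(blk$tampor))
      norm <- tampor(m, des, tp)
      # normalize on the full cohort, then subset to real (non-GIS) samples
      des_m <- des[match(colnames(norm), des$sample_id), ]
      keep <- !des_m$is_gis
      norm_sub <- abundance_matrix(unclass(norm)[, keep, drop = FALSE],
                                   "log2")
      reg_args <- blk$regress
      reg_args$seed <- stage_seed(config$seed, "harmonize")
      rp <- do.call(regress_params, as.list(reg_args))
      reg <- bootstrap_regress(norm_sub, des_m[keep, ], rp)
      f1 <- file.path(out, "cohort_harmonized.tsv")
      write_abundance_tsv(reg$matrix, f1)
      f2 <- file.path(out, "cohort_covariate_coefficients.tsv")
      utils::write.table(reg$coefficients, f2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      state$harmonized <- reg$matrix
      state$harmonized_design <- des_m[keep, ]
      list(n_proteins = nrow(reg$matrix), n_samples = ncol(reg$matrix),
           outputs = list(file_entry(f1, nrow(reg$matrix)),
                          file_entry(f2, nrow(reg$coefficients))))
    },
    network = {
      blk <- config$network
      if (is.null(state$harmonized)) {
        m <- read_abundance_tsv(file.path(out, "cohort_harmonized.tsv"))
        des <- read_design_tsv(file.path(out, "cohort_design.tsv"))
        des <- des[match(colnames(m), des$sample_id), ]
      } else {
        m <- state$harmonized; des <- state$harmonized_design
      }
      np <- do.call(network_params, as.list(blk$params))
      net <- build_network(m, np)
      labels <- net$modules$labels
      f1 <- file.path(out, "network_labels.tsv")
      utils::write.table(data.frame(protein_id = names(labels),
                                    module = labels),
                         f1, sep = "\t", quote = FALSE, row.names = FALSE)
      f2 <- file.path(out, "network_eigengenes.tsv")
      utils::write.table(data.frame(sample_id =
                                      rownames(net$modules$eigengenes),
                                    net$modules$eigengenes,
                                    check.names = FALSE),
                         f2, sep = "\t", quote = FALSE, row.names = FALSE)
      f3 <- file.path(out, "network_kme.tsv")
      utils::write.table(data.frame(protein_id = rownames(net$modules$kme$r),
                                    net$modules$kme$r, check.names = FALSE),
                         f3, sep = "\t", quote = FALSE, row.names = FALSE)
      tc <- module_trait_correlation(net$modules$eigengenes, des,
                                     traits = blk$traits)
      f4 <- file.path(out, "network_module_trait.tsv")
      utils::write.table(tc$table, f4, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      edge_files <- character(0)
      for (mid in sort(unique(labels[labels > 0]))) {
        ed <- top_tom_edges(net$tom, labels, mid, np)
        fe <- file.path(out, sprintf("network_edges_M%d.tsv", mid))
        write_edge_list(ed, fe)
        edge_files <- c(edge_files, fe)
      }
      state$modules <- net$modules
      sizes <- table(labels[labels > 0])
      list(n_modules = length(sizes),
           module_sizes = as.list(stats::setNames(as.integer(sizes),
                                                  paste0("M",
                                                         names(sizes)))),
           outputs = c(list(file_entry(f1, length(labels)),
                            file_entry(f2, nrow(net$modules$eigengenes)),
                            file_entry(f3, nrow(net$modules$kme$r)),
                            file_entry(f4, nrow(tc$table))),
                       lapply(edge_files, file_entry)))
    },
    integrate = {
      blk <- config$integrate
      if (is.null(state$modules)) {
        lab_df <- utils::read.delim(file.path(out, "network_labels.tsv"))
        labels <- stats::setNames(lab_df$module, lab_df$protein_id)
      } else {
        labels <- state$modules$labels
      }
      lists <- list()
      if (!is.null(blk$lists)) {
        for (nm in names(blk$lists)) lists[[nm]] <- read_id_list(blk$lists[[nm]])
      } else {
        hits <- file.path(out, "apms_enriched.txt")
        if (file.exists(hits)) lists$apms_enriched <- read_id_list(hits)
      }
      if (!length(lists))
        stop("integrate stage has no input lists")
      fet <- lists_vs_modules(lists, labels)
      f1 <- file.path(out, "integrate_module_fet.tsv")
      utils::write.table(fet$table, f1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs <- list(file_entry(f1, nrow(fet$table)))
      if (!is.null(blk$gmt)) {
        gmt <- read_gmt(blk$gmt)
        for (nm in names(lists)) {
          ge <- gmt_enrichment(lists[[nm]], gmt, names(labels),
                               min_set = blk$min_set %||% 1,
                               max_set = blk$max_set %||% Inf,
                               normalize = TRUE)
          fg <- file.path(out, sprintf("integrate_gmt_%s.tsv", nm))
          utils::write.table(ge, fg, sep = "\t", quote = FALSE,
                             row.names = FALSE)
          outputs <- c(outputs, list(file_entry(fg, nrow(ge))))
        }
      }
      if (length(lists) >= 2) {
        ov <- overlap_sets(lists)
        fo <- file.path(out, "integrate_overlaps.tsv")
        utils::write.table(ov, fo, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        outputs <- c(outputs, list(file_entry(fo, nrow(ov))))
      }
      n_sig <- sum(fet$table$q < 0.05, na.rm = TRUE)
      list(n_lists = length(lists), n_significant_cells = n_sig,
           outputs = outputs)
    },
    stop("unknown stage ", stage))
}

#' Summarize a pipeline artifact directory
#'
#' Reads the manifest, re-checks every recorded file checksum (mismatches
#' raise an integrity warning) and prints per-stage counts: proteins
#' retained, volcano class counts, module count and sizes, significant FET
#' cells.
#'
#' @param artifact_dir directory written by [run_pipeline()].
#' @return the summary list, invisibly.
#' @export
describe_run <- function(artifact_dir) {
  mf_path <- file.path(artifact_dir, "manifest.json")
  if (!file.exists(mf_path))
    stop("missing manifest: ", mf_path)
  mf <- jsonlite::read_json(mf_path)
  for (stage in names(mf$stages)) {
    for (o in mf$stages[[stage]]$outputs) {
      fp <- file.path(artifact_dir, o$file)
      if (!file.exists(fp)) {
        warning("integrity warning: ", o$file, " is missing")
      } else if (!identical(unname(tools::md5sum(fp)), o$md5)) {
        warning("integrity warning: checksum mismatch for ", o$file)
      }
    }
  }
  cat("proxinet run:", mf$status, "(seed", mf$seed, ")\n")
  summary <- list(status = mf$status, seed = mf$seed)
  for (stage in names(mf$stages)) {
    st <- mf$stages[[stage]]
    cat("stage", stage, "\n")
    if (stage == "apms") {
      cat("  proteins retained:", st$n_retained, "/", st$n_input, "\n")
      cat("  volcano counts: bait_enriched", st$counts$bait_enriched,
          "control_enriched", st$counts$control_enriched,
          "not_significant", st$counts$not_significant, "\n")
      summary$n_retained <- st$n_retained
      summary$enriched_count <- st$counts$bait_enriched
    }
    if (stage == "network") {
      cat("  modules:", st$n_modules, "; sizes:",
          paste(unlist(st$module_sizes), collapse = ", "), "\n")
      summary$module_count <- st$n_modules
      summary$module_sizes <- unlist(st$module_sizes)
    }
    if (stage == "integrate") {
      cat("  significant FET cells (q < 0.05):", st$n_significant_cells,
          "\n")
      summary$significant_fet_cells <- st$n_significant_cells
    }
  }
  invisible(summary)
}
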