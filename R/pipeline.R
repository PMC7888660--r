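## Pipeline orchestration: validated config, staged execution, md5 manifest.
## The exported functions are the programmatic command surface; a thin
## Rscript wrapper lives in inst/scripts/imodulon-pipeline.R.

#' Default pipeline configuration
#'
#' Returns the full default configuration as a nested list. Supply overrides
#' for any subset of fields; unknown fields raise an error. The same
#' structure round-trips through YAML or JSON (see [load_config()]).
#'
#' @param ... named overrides, e.g. `outdir = "out"`, `master_seed = 42`,
#'   `ica = list(n_runs = 20)`.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    outdir = "imodulonr_out",
    master_seed = 1L,
    # synthetic scenario (used by the simulate stage)
    simulate = list(
      n_genes = 1000L, n_components = 8L,
      genes_per_component = c(10L, 80L),
      n_conditions = 20L, replicates = 2L, activity_scale = 5,
      datasets = list(
        list(id = "D1", noise_sd = 0.05, gene_subset_fraction = 1,
             batch_shift_sd = 0),
        list(id = "D2", noise_sd = 0.05, gene_subset_fraction = 1,
             batch_shift_sd = 0)
      ),
      trn = list(dropout = 0.1, spurious_per_regulon = 5L)
    ),
    # real data: list of list(id, expression = path, metadata = path);
    # filled automatically by the simulate stage
    datasets = NULL,
    trn_path = NULL,
    go_path = NULL,
    preprocess = list(max_missing = 300L, min_replicate_r = 0.2),
    ica = list(n_runs = 100L, n_repetitions = 10L, tolerance = 1e-6,
               variance_target = 0.99, eps = 0.1, min_members = 50L,
               match_threshold = 0.7, max_iter = 500L),
    imodulons = list(grid_start = 200, grid_stop = 1000, grid_step = 50,
                     top_n = 20L, enrichment_fdr = 1e-5,
                     fallback_cutoff = 550),
    characterize = list(regulon_fdr = 1e-5, go_fdr = 0.01),
    compare = list(prune_threshold = 0.3, per_dataset = TRUE)
  )
  overrides <- list(...)
  merge_cfg <- function(base, over, path = "") {
    for (nm in names(over)) {
      if (!nm %in% names(base)) {
        stop("unknown config field: ", path, nm)
      }
      if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
          !is.null(names(base[[nm]])) && nm != "datasets") {
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]],
                                paste0(path, nm, "$"))
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  cfg <- merge_cfg(cfg, overrides)
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Load / save a pipeline configuration (YAML or JSON)
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return a `PipelineConfig`.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, raw)
}

#' @rdname load_config
#' @param config a `PipelineConfig`.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Validate pipeline inputs before running
#'
#' Checks file existence, table schemas, per-dataset reference conditions
#' and gene-universe consistency between expression data and annotations.
#' Never throws for data problems; returns a report instead.
#'
#' @param config a `PipelineConfig`.
#' @return data.frame with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows means fully consistent inputs.
#' @export
validate_inputs <- function(config) {
  issues <- list()
  add <- function(level, msg) {
    issues[[length(issues) + 1L]] <<- data.frame(level = level,
                                                 message = msg)
  }
  universe <- character(0)
  for (d in config$datasets) {
    if (!file.exists(d$expression %||% "")) {
      add("error", sprintf("dataset %s: expression file missing (%s)",
                           d$id, d$expression %||% "NULL"))
      next
    }
    if (!file.exists(d$metadata %||% "")) {
      add("error", sprintf("dataset %s: metadata file missing (%s)",
                           d$id, d$metadata %||% "NULL"))
      next
    }
    x <- tryCatch(read_expression_tsv(d$expression, d$id),
                  error = function(e) e)
    if (inherits(x, "error")) {
      add("error", sprintf("dataset %s: %s", d$id, conditionMessage(x)))
      next
    }
    meta <- tryCatch(read_sample_table(d$metadata), error = function(e) e)
    if (inherits(meta, "error")) {
      add("error", sprintf("dataset %s metadata: %s", d$id,
                           conditionMessage(meta)))
      next
    }
    universe <- union(universe, gene_ids(x))
    if (!any(meta$is_reference & meta$dataset_id == d$id)) {
      add("error", sprintf("dataset %s: no reference sample flagged", d$id))
    }
    extra <- setdiff(sample_ids(x), meta$sample_id)
    if (length(extra)) {
      add("error", sprintf("dataset %s: %d samples lack metadata rows",
                           d$id, length(extra)))
    }
  }
  if (!is.null(config$trn_path)) {
    if (!file.exists(config$trn_path)) {
      add("error", sprintf("TRN file missing (%s)", config$trn_path))
    } else if (length(universe)) {
      trn <- read_trn(config$trn_path)
      absent <- setdiff(unique(unlist(trn)), universe)
      if (length(absent)) {
        add("warning", sprintf(
          "%d TRN genes absent from the expression universe; they are dropped during harmonization",
          length(absent)))
      }
    }
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(level = character(0), message = character(0))
  rownames(out) <- NULL
  out
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order: `simulate` (synthetic compendium
#' + TRN written to disk), `preprocess` (QC filters, gene intersection,
#' reference centering, concatenation), `decompose` (consensus ICA of the
#' combined compendium and, when comparison is requested, of each dataset),
#' `extract` (cutoff optimization + iModulon extraction), `characterize`
#' (regulon/GO enrichment and categories), `compare` (cross-dataset RBH
#' graph) and `activities` (replicate reproducibility summary). Every output
#' file is recorded in a manifest with its md5 checksum; rerunning with an
#' identical config and seed reproduces identical checksums.
#'
#' @param config a `PipelineConfig` (see [pipeline_config()]).
#' @param stages character subset of
#'   `c("simulate","preprocess","decompose","extract","characterize",
#'   "compare","activities")`; defaults to all.
#' @return invisibly, a list with the manifest data.frame and the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "preprocess", "decompose",
                                    "extract", "characterize", "compare",
                                    "activities")) {
  all_stages <- c("simulate", "preprocess", "decompose", "extract",
                  "characterize", "compare", "activities")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  issues <- validate_inputs(config)
  if (!"simulate" %in% stages && any(issues$level == "error")) {
    stop("invalid inputs:\n  ",
         paste(issues$message[issues$level == "error"], collapse = "\n  "))
  }
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(paths, stage) {
    for (p in paths) {
      manifest[[length(manifest) + 1L]] <<- data.frame(
        file = p, md5 = unname(tools::md5sum(p)), stage = stage)
    }
  }
  state <- list()
  seeds <- derive_seeds(config$master_seed, 64L)

  if ("simulate" %in% stages) {
    sc <- config$simulate
    gt <- make_ground_truth(sc$n_genes, sc$n_components,
                            sc$genes_per_component, sc$n_conditions,
                            sc$replicates, sc$activity_scale,
                            seed = seeds[1])
    ds_cfg <- list()
    for (i in seq_along(sc$datasets)) {
      d <- sc$datasets[[i]]
      r <- render_dataset(gt, d$id, noise_sd = d$noise_sd,
                          gene_subset_fraction = d$gene_subset_fraction,
                          batch_shift_sd = d$batch_shift_sd,
                          seed = seeds[1 + i])
      gt <- r$ground_truth
      pe <- file.path(out, paste0("expression_", d$id, ".tsv"))
      pm <- file.path(out, paste0("samples_", d$id, ".tsv"))
      write_expression_tsv(r$x, pe)
      write_sample_table(r$meta, pm)
      note(c(pe, pm), "simulate")
      ds_cfg[[i]] <- list(id = d$id, expression = pe, metadata = pm)
    }
    trn <- make_trn(gt, dropout = sc$trn$dropout,
                    spurious_per_regulon = sc$trn$spurious_per_regulon,
                    seed = seeds[20])
    pt <- file.path(out, "trn.tsv")
    write_trn(trn, pt)
    note(pt, "simulate")
    note(write_ground_truth(gt, file.path(out, "ground_truth")), "simulate")
    config$datasets <- ds_cfg
    config$trn_path <- pt
    state$ground_truth <- gt
  }

  if ("preprocess" %in% stages) {
    if (is.null(config$datasets)) {
      stop("no datasets configured; run the simulate stage first or point ",
           "config$datasets at expression/metadata files")
    }
    xs <- list(); metas <- list()
    for (d in config$datasets) {
      x <- read_expression_tsv(d$expression, d$id)
      meta <- read_sample_table(d$metadata)
      x <- filter_profiles_missing(x, config$preprocess$max_missing)
      x <- filter_genes_missing(x)
      fr <- filter_replicate_correlation(x, meta,
                                         config$preprocess$min_replicate_r)
      xs[[d$id]] <- fr$x
      metas[[d$id]] <- fr$meta
    }
    if (length(xs) >= 2L) xs <- stats::setNames(intersect_genes(xs), names(xs))
    centered <- Map(center_to_reference, xs, metas)
    comb <- concatenate_datasets(centered, metas)
    px <- file.path(out, "compendium.tsv")
    pm <- file.path(out, "compendium_samples.tsv")
    write_expression_tsv(comb$x, px)
    write_sample_table(comb$meta, pm)
    note(c(px, pm), "preprocess")
    state$centered <- centered
    state$metas <- metas
    state$compendium <- comb
  }

  if ("decompose" %in% stages) {
    if (is.null(state$compendium)) stop("run the preprocess stage first")
    ic <- config$ica
    dec <- run_robust_ica(state$compendium$x, n_runs = ic$n_runs,
                          n_repetitions = ic$n_repetitions,
                          tolerance = ic$tolerance,
                          variance_target = ic$variance_target,
                          eps = ic$eps, min_members = ic$min_members,
                          match_threshold = ic$match_threshold,
                          max_iter = ic$max_iter, seed = seeds[30])
    note(write_decomposition(dec, file.path(out, "decomposition_combined")),
         "decompose")
    state$decomposition <- dec
    if (isTRUE(config$compare$per_dataset) && length(state$centered) >= 2L) {
      state$per_dataset <- list()
      for (i in seq_along(state$centered)) {
        ds <- names(state$centered)[i]
        di <- run_robust_ica(state$centered[[i]], n_runs = ic$n_runs,
                             n_repetitions = ic$n_repetitions,
                             tolerance = ic$tolerance,
                             variance_target = ic$variance_target,
                             eps = ic$eps, min_members = ic$min_members,
                             match_threshold = ic$match_threshold,
                             max_iter = ic$max_iter, seed = seeds[30 + i])
        note(write_decomposition(di, file.path(out, paste0("decomposition_", ds))),
             "decompose")
        state$per_dataset[[ds]] <- di
      }
    }
  }

  if ("extract" %in% stages) {
    if (is.null(state$decomposition)) stop("run the decompose stage first")
    imc <- config$imodulons
    trn <- if (!is.null(config$trn_path)) read_trn(config$trn_path) else NULL
    cutoff <- imc$fallback_cutoff
    if (!is.null(trn)) {
      opt <- tryCatch(
        optimize_cutoff(state$decomposition$S, trn,
                        grid_start = imc$grid_start,
                        grid_stop = imc$grid_stop,
                        grid_step = imc$grid_step,
                        top_n = imc$top_n, fdr = imc$enrichment_fdr),
        error = function(e) {
          warning("cutoff optimization failed (", conditionMessage(e),
                  "); using fallback cutoff ", imc$fallback_cutoff)
          NULL
        })
      if (!is.null(opt)) {
        cutoff <- opt$cutoff
        pg <- file.path(out, "cutoff_grid.tsv")
        utils::write.table(opt$table, pg, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        note(pg, "extract")
        state$cutoff_table <- opt$table
      }
    } else {
      warning("no TRN available; using fallback cutoff ", cutoff)
    }
    ims <- extract_all_imodulons(state$decomposition, cutoff)
    note(write_imodulons(ims, state$decomposition$S, out), "extract")
    state$cutoff <- cutoff
    state$imodulons <- ims
  }

  if ("characterize" %in% stages) {
    if (is.null(state$imodulons)) stop("run the extract stage first")
    trn <- if (!is.null(config$trn_path)) read_trn(config$trn_path) else NULL
    go <- if (!is.null(config$go_path)) read_gmt(config$go_path) else NULL
    universe <- length(state$decomposition$gene_ids)
    reg_res <- if (!is.null(trn)) {
      enrich_imodulons(state$imodulons, trn, universe,
                       fdr = config$characterize$regulon_fdr)
    } else NULL
    go_res <- if (!is.null(go)) {
      enrich_imodulons(state$imodulons, go, universe,
                       fdr = config$characterize$go_fdr)
    } else NULL
    state$imodulons <- lapply(state$imodulons, categorize,
                              regulon_results = reg_res,
                              go_results = go_res,
                              regulon_fdr = config$characterize$regulon_fdr,
                              go_fdr = config$characterize$go_fdr)
    if (!is.null(reg_res)) {
      pr <- file.path(out, "enrichments.tsv")
      write_enrichments(reg_res, pr)
      note(pr, "characterize")
    }
    pc <- file.path(out, "categories.tsv")
    utils::write.table(
      data.frame(
        component_id = vapply(state$imodulons, `[[`, character(1), "component_id"),
        category = vapply(state$imodulons, `[[`, character(1), "category"),
        name = vapply(state$imodulons, `[[`, character(1), "name"),
        size = lengths(lapply(state$imodulons, `[[`, "gene_set"))),
      pc, sep = "\t", quote = FALSE, row.names = FALSE)
    note(pc, "characterize")
  }

  if ("compare" %in% stages) {
    decs <- state$per_dataset
    if (is.null(decs)) {
      # fall back to decompositions previously written to disk
      dirs <- list.dirs(out, recursive = FALSE)
      dirs <- dirs[grepl("decomposition_", dirs) &
                     !grepl("combined", dirs)]
      if (length(dirs) >= 2L) {
        decs <- lapply(dirs, read_decomposition)
        names(decs) <- sub(".*decomposition_", "", dirs)
      }
    }
    if (is.null(decs) || length(decs) < 2L) {
      stop("comparison needs at least 2 per-dataset decompositions; ",
           "run decompose first with compare$per_dataset = TRUE")
    }
    g <- build_rbh_graph(decs, config$compare$prune_threshold)
    note(write_rbh_graph(g, out), "compare")
    cl <- find_clusters(g)
    pc <- file.path(out, "rbh_clusters.tsv")
    utils::write.table(cl, pc, sep = "\t", quote = FALSE, row.names = FALSE)
    note(pc, "compare")
    state$rbh <- g
    state$clusters <- cl
  }

  if ("activities" %in% stages) {
    if (is.null(state$decomposition)) stop("run the decompose stage first")
    rsd <- replicate_rsd(state$decomposition$A, state$compendium$meta)
    pr <- file.path(out, "replicate_rsd.tsv")
    utils::write.table(rsd, pr, sep = "\t", quote = FALSE, row.names = FALSE)
    note(pr, "activities")
    state$rsd <- rsd
  }

  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(file = character(0), md5 = character(0), stage = character(0))
  rownames(manifest) <- NULL
  pj <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, pj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(manifest = manifest, state = state, config = config))
}
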