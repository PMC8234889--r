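#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Either a `sim` block
#' (a [sim_config()]) or a `paths` list pointing at existing TSV inputs
#' (`normal`, `tumor`, `clinical`, optionally `mirna`, `biotypes`,
#' `network`) must be supplied.
#'
#' @param sim A [sim_config()] describing the synthetic cohort, or `NULL`
#'   when `paths` is given.
#' @param paths Named list of input TSV paths, or `NULL` to simulate.
#' @param bootstrap_B Bootstrap resamples for the stability filter.
#' @param retain_frac Minimum bootstrap stability to retain a call.
#' @param alpha Per-model significance level for the age coefficient.
#' @param beta Diffusion-kernel parameter.
#' @param min_size Minimum module size for the tree cut.
#' @param folds,reps Cross-validation folds and repetitions for the
#'   prediction comparison.
#' @param network Planted-partition parameters for the simulated
#'   interaction network (`n_modules`, `module_size`, `p_in`, `p_out`);
#'   ignored when a network path is given.
#' @param index_mode Index mode for [compute_index()].
#' @param seed Global seed for every stage not covered by `sim$seed`.
#' @return Object of class `agesurv_config`.
#' @export
agesurv_config <- function(sim = sim_config(), paths = NULL,
                           bootstrap_B = 100, retain_frac = 0.5,
                           alpha = 0.05, beta = 1, min_size = 5,
                           folds = 5, reps = 100,
                           network = list(n_modules = 6, module_size = 50,
                                          p_in = 0.25, p_out = 0.02),
                           index_mode = "zscore", seed = 1L) {
  cfg <- list(sim = sim, paths = paths, bootstrap_B = as.integer(bootstrap_B),
              retain_frac = retain_frac, alpha = alpha, beta = beta,
              min_size = as.integer(min_size), folds = as.integer(folds),
              reps = as.integer(reps), network = network,
              index_mode = index_mode, seed = as.integer(seed))
  if (is.null(sim) && is.null(paths)) {
    stop("either a sim block or input paths must be given", call. = FALSE)
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (cfg$bootstrap_B < 0 || cfg$retain_frac < 0 || cfg$retain_frac > 1 ||
      cfg$beta <= 0 || cfg$min_size < 2 || cfg$folds < 2 || cfg$reps < 1) {
    stop("pipeline parameter out of range", call. = FALSE)
  }
  structure(cfg, class = "agesurv_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [agesurv_config()] arguments; a `sim` mapping
#' is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return An `agesurv_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(agesurv_config, y)
}

preflight <- function(config) {
  if (!is.null(config$paths)) {
    need <- c("normal", "tumor", "clinical")
    miss <- setdiff(need, names(config$paths))
    if (length(miss) > 0) {
      stop("pre-flight: missing input path(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(config$paths)) {
      if (!file.exists(config$paths[[nm]])) {
        stop("pre-flight: input file not found: ", config$paths[[nm]],
             call. = FALSE)
      }
    }
  }
  invisible(config)
}

validate_clinical <- function(clinical) {
  need <- c("sample_id", "age_years", "time_days", "event")
  miss <- setdiff(need, names(clinical))
  if (length(miss) > 0) {
    stop("pre-flight: clinical table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(clinical$time_days < 0) || !all(clinical$event %in% c(0, 1))) {
    stop("pre-flight: clinical table has invalid time/event values",
         call. = FALSE)
  }
  invisible(clinical)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, preprocessing, aging-transcript selection with
#' bootstrap stability, index construction, survival linkage, paired DEG
#' calling, network module detection with a survival screen, and the
#' five-way survival-prediction comparison. All randomness derives from
#' the seeds in the configuration, so two runs with the same configuration
#' produce byte-identical outputs.
#'
#' @param config An [agesurv_config()] or the path to a YAML file for
#'   [read_config()].
#' @param out_dir Output directory (created if needed); all result TSVs,
#'   the resolved configuration and `report.md` are written there.
#' @param write_inputs Also write the (simulated) input matrices,
#'   clinical, biotype, truth and network tables.
#' @return Object of class `run_report`: stage summaries, headline tables
#'   and output paths.
#' @export
run_pipeline <- function(config = agesurv_config(), out_dir,
                         write_inputs = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "agesurv_config"))
  preflight(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name) message("== stage: ", name, " ==")

  # -- data ------------------------------------------------------------
  stage("data")
  truth <- network_truth <- NULL
  if (is.null(config$paths)) {
    cohort <- simulate_cohort(config$sim)
    normal <- cohort$normal_expr
    tumor <- cohort$tumor_expr
    clinical <- cohort$clinical
    truth <- cohort$truth
    mirna <- simulate_mirna(config$sim)
    biotypes <- tibble::tibble(gene_id = truth$gene_id,
                               biotype = "protein_coding")
    nw <- config$network
    n_nodes <- nw$n_modules * nw$module_size
    stopifnot(n_nodes <= nrow(truth))
    net_sim <- simulate_ppi(nw$n_modules, nw$module_size, nw$p_in, nw$p_out,
                            seed = config$seed + 7L,
                            node_ids = truth$gene_id[seq_len(n_nodes)])
    net_edges <- net_sim$edges
    network_truth <- net_sim$truth_modules
  } else {
    normal <- read_expr_tsv(config$paths$normal)
    tumor <- read_expr_tsv(config$paths$tumor)
    clinical <- readr::read_tsv(config$paths$clinical, show_col_types = FALSE,
                                progress = FALSE)
    mirna <- if (!is.null(config$paths$mirna)) {
      read_expr_tsv(config$paths$mirna)
    }
    biotypes <- if (!is.null(config$paths$biotypes)) {
      readr::read_tsv(config$paths$biotypes, show_col_types = FALSE,
                      progress = FALSE)
    } else {
      tibble::tibble(gene_id = normal$gene_id, biotype = "protein_coding")
    }
    net_edges <- if (!is.null(config$paths$network)) {
      read_edge_list(config$paths$network)
    }
  }
  validate_clinical(clinical)
  ages <- clinical$age_years

  # -- preprocess ------------------------------------------------------
  stage("preprocess")
  normal_f <- filter_low_expression(filter_protein_coding(normal, biotypes))
  tumor_f <- filter_low_expression(filter_protein_coding(tumor, biotypes))
  shared <- intersect(normal_f$gene_id, tumor_f$gene_id)
  normal_f <- dplyr::filter(normal_f, .data$gene_id %in% shared)
  tumor_f <- dplyr::filter(tumor_f, .data$gene_id %in% shared)
  mirna_f <- if (!is.null(mirna)) quantile_normalize(filter_mirna(mirna))

  # -- aging -----------------------------------------------------------
  stage("aging")
  aging <- bootstrap_stability(normal_f, ages, B = config$bootstrap_B,
                               retain_frac = config$retain_frac,
                               seed = config$seed, alpha = config$alpha)
  up <- aging$gene_id[aging$direction == "increasing"]
  dn <- aging$gene_id[aging$direction == "decreasing"]
  idx_tbl <- tibble::tibble(sample_id = clinical$sample_id)
  idx_tbl$increasing_index <- if (length(up) > 0) {
    compute_index(normal_f, up, config$index_mode)$index
  } else NA_real_
  idx_tbl$decreasing_index <- if (length(dn) > 0) {
    compute_index(normal_f, dn, config$index_mode)$index
  } else NA_real_

  # -- survival --------------------------------------------------------
  stage("survival")
  surv_row <- function(nm, v) {
    if (all(is.na(v))) return(NULL)
    fit <- fit_cox_univariate(clinical, v, term = nm)
    lr <- logrank_test(clinical, median_split(v))
    tibble::tibble(covariate = nm, hazard_ratio = fit$hr,
                   p_wald = fit$p_value, p_logrank = lr$p_value,
                   n = fit$n, n_event = fit$n_event)
  }
  survival_tbl <- dplyr::bind_rows(
    surv_row("increasing_index", idx_tbl$increasing_index),
    surv_row("decreasing_index", idx_tbl$decreasing_index),
    surv_row("age_years", ages)
  )

  # -- deg -------------------------------------------------------------
  stage("deg")
  degs <- paired_deg(normal_f, tumor_f)

  # -- modules ---------------------------------------------------------
  stage("modules")
  modules <- NULL
  screen <- tibble::tibble()
  if (!is.null(net_edges)) {
    aging_genes <- c(up, dn)
    modules <- tryCatch(
      detect_modules(net_edges, genes = aging_genes, beta = config$beta,
                     min_size = config$min_size),
      error = function(e) {
        message("module detection skipped: ", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(modules)) {
      screen <- module_survival_screen(modules, aging, normal_f, clinical,
                                       mode = config$index_mode)
    }
  } else {
    message("no network available: module stage skipped")
  }

  # -- predict ---------------------------------------------------------
  stage("predict")
  prediction <- compare_feature_sets(normal_f, tumor_f, clinical, aging,
                                     degs, folds = config$folds,
                                     reps = config$reps,
                                     seed = config$seed,
                                     mode = config$index_mode)

  # -- outputs ---------------------------------------------------------
  stage("report")
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(tibble::as_tibble(aging), p("aging_genes.tsv"),
                   progress = FALSE)
  readr::write_tsv(idx_tbl, p("index.tsv"), progress = FALSE)
  readr::write_tsv(survival_tbl, p("survival.tsv"), progress = FALSE)
  write_deg_tsv(degs, p("deg.tsv"))
  if (!is.null(modules)) {
    readr::write_tsv(tibble::as_tibble(modules), p("modules.tsv"),
                     progress = FALSE)
    readr::write_tsv(screen, p("module_survival.tsv"), progress = FALSE)
  }
  readr::write_tsv(dplyr::select(prediction, -"aucs"), p("prediction.tsv"),
                   progress = FALSE)
  readr::write_tsv(
    tidyr::unnest(dplyr::select(prediction, "config", "aucs"), "aucs"),
    p("prediction_aucs.tsv"), progress = FALSE)
  writeLines(yaml::as.yaml(resolved_config(config)), p("config.yaml"))
  if (write_inputs) {
    write_expr_tsv(normal, p("normal_expr.tsv"))
    write_expr_tsv(tumor, p("tumor_expr.tsv"))
    readr::write_tsv(clinical, p("clinical.tsv"), progress = FALSE)
    readr::write_tsv(biotypes, p("biotypes.tsv"), progress = FALSE)
    if (!is.null(mirna)) write_expr_tsv(mirna, p("mirna.tsv"))
    if (!is.null(truth)) readr::write_tsv(truth, p("truth.tsv"),
                                          progress = FALSE)
    if (!is.null(net_edges)) readr::write_tsv(net_edges, p("network.tsv"),
                                              progress = FALSE)
    if (!is.null(network_truth)) {
      readr::write_tsv(network_truth, p("network_truth.tsv"),
                       progress = FALSE)
    }
  }

  report <- structure(list(
    counts = list(
      samples = nrow(clinical),
      genes_in = nrow(normal), genes_filtered = nrow(normal_f),
      aging_up = length(up), aging_down = length(dn),
      deg_up = sum(degs$call == "up"), deg_down = sum(degs$call == "down"),
      modules = if (is.null(modules)) 0L else {
        length(unique(stats::na.omit(modules$module)))
      }
    ),
    survival = survival_tbl,
    module_screen = screen,
    prediction = dplyr::select(prediction, -"aucs"),
    out_dir = out_dir,
    files = sort(list.files(out_dir))
  ), class = "run_report")
  writeLines(format_report(report), p("report.md"))
  report$files <- sort(list.files(out_dir))
  report
}

resolved_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$sim)) cfg$sim <- unclass(cfg$sim)
  cfg
}

format_report <- function(x) {
  cn <- x$counts
  tsv_block <- function(df) {
    c("```", readr::format_tsv(dplyr::mutate(df, dplyr::across(
      dplyr::where(is.numeric), ~ signif(.x, 5)))), "```")
  }
  c("# Pipeline run report",
    "",
    sprintf("- samples: %d", cn$samples),
    sprintf("- genes: %d in, %d after filters", cn$genes_in,
            cn$genes_filtered),
    sprintf("- aging transcripts: %d increasing, %d decreasing",
            cn$aging_up, cn$aging_down),
    sprintf("- paired DEGs: %d up, %d down", cn$deg_up, cn$deg_down),
    sprintf("- network modules: %d", cn$modules),
    "",
    "## Survival linkage", "", tsv_block(x$survival), "",
    if (nrow(x$module_screen) > 0) {
      c("## Module survival screen", "", tsv_block(x$module_screen), "")
    },
    "## Survival prediction (mean CV AUC)", "", tsv_block(x$prediction))
}

#' @export
print.run_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Checksums of a pipeline output directory
#'
#' MD5 of every regular file, named by relative path — a compact way to
#' verify byte-identical reproduction of a run.
#'
#' @param dir Output directory.
#' @return Named character vector of MD5 hashes, sorted by file name.
#' @export
output_checksums <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  md5 <- tools::md5sum(files)
  names(md5) <- sub(paste0("^", dir, "/?"), "", names(md5))
  md5
}
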