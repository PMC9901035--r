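#' Run the full annotation pipeline from a configuration
#'
#' Chains marker discovery on the reference, cell-type scoring of reference
#' and query, consensus annotation of the query, and evaluation, writing
#' four artifacts into the output directory: \code{markers.csv} (wide
#' marker-table CSV), \code{scores.tsv} (reference and query score matrices
#' stacked, with a \code{source} column), \code{annotation.tsv} and
#' \code{report.json}. Every stage is logged with its parameters and
#' duration. One global seed derives fixed per-stage offsets so stages are
#' independently reproducible.
#'
#' @param config a named list or a path to a YAML/JSON file. Recognized
#'   keys (all optional unless noted): \code{output} (required),
#'   \code{reference$mtx} or \code{reference$dense} (required),
#'   \code{reference$labels} (required unless \code{markers} given),
#'   \code{query$mtx}/\code{query$dense} (required), \code{query$labels}
#'   (truth, enables evaluation), \code{query$batches} (per-cell batch TSV,
#'   enables entropy mixing), \code{markers} (pre-built table CSV),
#'   \code{marker_discovery} (\code{methods}, \code{scheme}, \code{top_k},
#'   \code{alpha}), \code{scoring} (\code{mode}, \code{percentile},
#'   \code{use_weights}), \code{clustering} (\code{resolutions},
#'   \code{n_neighbors}, \code{metric}), \code{annotation}
#'   (\code{n_batches}, \code{n_workers}, \code{unassigned_threshold}),
#'   \code{evaluation} (\code{n_regions}, \code{region_size}),
#'   \code{preprocess} (\code{scale}), \code{seed}.
#' @param quiet suppress stage logging.
#' @return Invisibly, a list with the fitted \code{"masi"}, the query
#'   annotation and the metrics report (NULL without truth labels).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (is.character(config)) read_config(config) else config
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  get_cfg <- function(path, default) {
    v <- cfg
    for (k in path) {
      if (is.null(v[[k]])) return(default)
      v <- v[[k]]
    }
    v
  }
  # ---- validation before any compute ----
  if (is.null(cfg$output)) stop("config key 'output' is required")
  for (key in list(c("reference", "mtx"), c("reference", "dense"),
                   c("reference", "labels"), c("query", "mtx"),
                   c("query", "dense"), c("query", "labels"),
                   c("query", "batches"), "markers")) {
    p <- get_cfg(key, NULL)
    if (!is.null(p) && !file.exists(p))
      stop("configured path does not exist [", paste(key, collapse = "."),
           "]: ", p)
  }
  if (is.null(get_cfg(c("reference", "mtx"), NULL)) &&
      is.null(get_cfg(c("reference", "dense"), NULL)))
    stop("config requires reference$mtx or reference$dense")
  if (is.null(get_cfg(c("query", "mtx"), NULL)) &&
      is.null(get_cfg(c("query", "dense"), NULL)))
    stop("config requires query$mtx or query$dense")
  seed <- get_cfg("seed", 0)
  dir.create(cfg$output, showWarnings = FALSE, recursive = TRUE)

  read_expr <- function(node) {
    if (!is.null(node$mtx)) read_mtx(node$mtx) else read_dense(node$dense)
  }
  stage <- function(name, fun) {
    t0 <- Sys.time()
    out <- fun()
    log_msg("[%s] done in %.1fs", name,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  ref <- stage("read reference", function() read_expr(cfg$reference))
  query <- stage("read query", function() read_expr(cfg$query))
  ref_labels <- if (!is.null(cfg$reference$labels))
    read_labels(cfg$reference$labels, ref$cell_ids)
  markers <- if (!is.null(cfg$markers))
    stage("read markers", function() read_marker_table(cfg$markers))

  fit <- stage("fit (markers + reference scores + centroids)", function()
    masi(ref, ref_labels, markers = markers,
         methods = unlist(get_cfg(c("marker_discovery", "methods"),
                                  c("wilcoxon", "welch_t", "logfc", "cosg"))),
         scheme = get_cfg(c("marker_discovery", "scheme"), "top_k_rra"),
         top_k = get_cfg(c("marker_discovery", "top_k"), 20),
         alpha = get_cfg(c("marker_discovery", "alpha"), 0.05),
         mode = get_cfg(c("scoring", "mode"), "pliner"),
         X = get_cfg(c("scoring", "percentile"), 0.25),
         use_weights = get_cfg(c("scoring", "use_weights"), TRUE),
         scale = get_cfg(c("preprocess", "scale"), 10000)))

  ann <- stage("annotate query", function()
    predict(fit, query,
            n_batches = get_cfg(c("annotation", "n_batches"), 1),
            n_workers = get_cfg(c("annotation", "n_workers"), 1),
            resolutions = unlist(get_cfg(c("clustering", "resolutions"),
                                         c(3, 5, 7))),
            n_neighbors = unlist(get_cfg(c("clustering", "n_neighbors"),
                                         c(5, 10, 15))),
            metric = get_cfg(c("clustering", "metric"), "cosine"),
            seed = seed + 100,
            unassigned_threshold = get_cfg(c("annotation",
                                             "unassigned_threshold"), NULL)))

  report <- NULL
  if (!is.null(cfg$query$labels)) {
    truth <- read_labels(cfg$query$labels, query$cell_ids)
    batches <- if (!is.null(cfg$query$batches))
      read_labels(cfg$query$batches, query$cell_ids)
    report <- stage("evaluate", function()
      evaluate_annotation(ann$label, truth,
                          representation = attr(ann, "scores"),
                          batch = batches,
                          n_regions = get_cfg(c("evaluation", "n_regions"), 50),
                          region_size = get_cfg(c("evaluation", "region_size"),
                                                100),
                          seed = seed + 200))
  }

  stage("write artifacts", function() {
    write_marker_table(fit$markers, file.path(cfg$output, "markers.csv"))
    qs <- attr(ann, "scores")
    stacked <- data.frame(cell_id = c(rownames(fit$scores), rownames(qs)),
                          source = rep(c("reference", "query"),
                                       c(nrow(fit$scores), nrow(qs))),
                          rbind(as.data.frame(fit$scores),
                                as.data.frame(qs)),
                          check.names = FALSE)
    utils::write.table(stacked, file.path(cfg$output, "scores.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_annotation(ann, file.path(cfg$output, "annotation.tsv"))
    rep_out <- if (is.null(report)) list(note = "no truth labels supplied")
    else c(unclass(report), list(meta = attr(report, "meta")))
    jsonlite::write_json(rep_out, file.path(cfg$output, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    NULL
  })
  invisible(list(fit = fit, annotation = ann, report = report))
}

# YAML with JSON accepted (JSON is a YAML subset for our configs).
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}
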