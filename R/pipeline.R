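#' Read a run configuration file
#'
#' JSON (always available) or YAML (if the `yaml` package is installed),
#' chosen by file extension.  The configuration is a named list; see
#' [run_delimit()] and [run_dec()] for the recognised fields.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("config error: YAML config requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

.require_file <- function(path, what) {
  if (!file.exists(path))
    stop("config error: ", what, " file not found: ", path)
  path
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

.provenance <- function(config, seed = NULL) {
  list(config_hash = .config_hash(config),
       seed = seed,
       r_version = as.character(getRversion()),
       package_version = as.character(utils::packageVersion("phylodelim")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

.load_trees_from_config <- function(config) {
  dialect <- if (is.null(config$dialect)) "mlbp/bipp" else config$dialect
  trees <- if (!is.null(config$trees)) config$trees
    else lapply(config$tree_files, function(f)
      parse_tree(paste(readLines(.require_file(f, "tree")), collapse = "\n"),
                 dialect = dialect))
  combined <- if (!is.null(config[["combined_tree"]])) config$combined_tree
    else parse_tree(paste(readLines(
      .require_file(config$combined_tree_file, "combined tree")),
      collapse = "\n"), dialect = dialect)
  list(trees = trees, combined = combined)
}

#' Run the GCPSR species-delimitation pipeline
#'
#' Loads per-locus trees, the combined tree and (optionally) alignments;
#' restricts the gene trees to their common taxa; computes the distance
#' matrix for the singleton rule; runs [delimit()]; and writes the criterion
#' table (TSV), the partition and decision report (JSON), the distance
#' matrix (CSV) and a provenance record into `config$out_dir`.
#'
#' Recognised config fields: `tree_files`/`trees`, `combined_tree_file`/
#' `combined_tree`, `dialect`, `alignment_files`/`alignments` (concatenated
#' column-wise for the distance matrix), `taxon_map` (data frame or file with
#' columns label/sample), `thresholds` (`mlbp_min`, `bipp_min`), `distance`
#' (`model`, `gamma_shape`), `singletons`, `out_dir`.
#'
#' @param config named list or path to a configuration file.
#' @return the `"delimitation"` object, invisibly, with an `"outputs"`
#'   attribute listing the files written.
#' @export
run_delimit <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  loaded <- .load_trees_from_config(config)
  trees <- loaded$trees
  common <- Reduce(intersect, lapply(trees, function(t) t$tip.label))
  if (!length(common)) stop("data error: gene trees share no taxa")
  trees <- restrict_to_common_taxa(trees, common)
  dm <- NULL
  map <- NULL
  if (!is.null(config$taxon_map)) {
    tm <- config$taxon_map
    if (is.character(tm))
      tm <- utils::read.table(.require_file(tm, "taxon map"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
    map <- taxon_map(tm$label, tm$sample,
                     if ("group" %in% names(tm)) tm$group else NA)
  }
  aln <- NULL
  if (!is.null(config$alignments)) {
    aln <- do.call(cbind, config$alignments)
  } else if (!is.null(config$alignment_files)) {
    parts <- lapply(config$alignment_files, function(f)
      read_alignment(.require_file(f, "alignment")))
    labs <- rownames(parts[[1]])
    parts <- lapply(parts, function(p) {
      miss <- setdiff(labs, rownames(p))
      if (length(miss))
        stop("data error: alignments disagree on labels: ",
             paste(miss, collapse = ", "))
      p[labs, , drop = FALSE]
    })
    aln <- do.call(cbind, parts)
  }
  dcfg <- dist_config(
    model = if (is.null(config$distance$model)) "TN93" else config$distance$model,
    gamma_shape = if (is.null(config$distance$gamma_shape)) 1
                  else config$distance$gamma_shape)
  if (!is.null(aln)) dm <- distance_matrix(aln, dcfg)
  thr <- if (is.null(config$thresholds)) support_thresholds()
    else support_thresholds(config$thresholds$mlbp_min, config$thresholds$bipp_min)
  singletons <- if (is.null(config$singletons)) character()
                else as.character(config$singletons)
  res <- delimit(trees, loaded$combined, dm = dm, thresholds = thr,
                 singletons = singletons, map = map)
  outputs <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(config$out_dir, "criterion_table.tsv")
    write_criterion_table(res, f1)
    f2 <- file.path(config$out_dir, "partition.json")
    jsonlite::write_json(list(
      assignment = as.list(res$partition$assignment),
      provenance = res$partition$provenance,
      singleton_report = res$singleton_report,
      conflicts = if (nrow(res$conflicts))
        res$conflicts[, c("locus_a", "locus_b", "mlbp_a", "bipp_a",
                          "mlbp_b", "bipp_b")] else list(),
      run = .provenance(config[!vapply(config, is.object, TRUE)])),
      f2, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    outputs <- c(f1, f2)
    if (!is.null(dm)) {
      f3 <- file.path(config$out_dir, "distances.csv")
      write_distance_csv(dm, f3)
      outputs <- c(outputs, f3)
    }
  }
  attr(res, "outputs") <- outputs
  invisible(res)
}

.geo_from_config <- function(g) {
  if (inherits(g, "dec_geography")) return(g)
  areas <- as.character(g$areas)
  epochs <- NULL
  if (!is.null(g$epochs)) {
    epochs <- lapply(g$epochs, function(ep) {
      m <- ep$m
      if (is.null(m)) m <- matrix(1, length(areas), length(areas))
      m <- matrix(as.numeric(unlist(m)), length(areas), length(areas),
                  byrow = is.list(m), dimnames = list(areas, areas))
      list(start = ep$start, end = if (is.null(ep$end)) Inf else ep$end, m = m)
    })
  }
  geography(areas,
            max_range_size = if (is.null(g$max_range_size)) length(areas)
                             else g$max_range_size,
            excluded_ranges = if (is.null(g$excluded_ranges)) list()
                              else lapply(g$excluded_ranges, function(x)
                                strsplit(x, "")[[1]]),
            epochs = epochs)
}

#' Run the DEC ancestral-range pipeline
#'
#' Loads a chronogram, tip ranges and a geography; fits the dispersal and
#' extinction rates by maximum likelihood; computes the ancestral split
#' tables; and writes the ranked splits (TSV), the best-split annotated
#' newick, and the fit with its convergence diagnostics (JSON).
#'
#' Recognised config fields: `chronogram_file`/`chronogram`, `ranges_file`
#' (TSV: tip, range)/`tip_ranges`, `geography` (list: `areas`,
#' `max_range_size`, `excluded_ranges` as area strings, `epochs`),
#' `root_prior`, `bounds`, `starts`, `out_dir`.
#'
#' @param config named list or path to a configuration file.
#' @return list with `fit` and `splits`, invisibly, with an `"outputs"`
#'   attribute.
#' @export
run_dec <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  chrono <- if (!is.null(config[["chronogram"]])) config$chronogram
    else ape::read.tree(.require_file(config$chronogram_file, "chronogram"))
  tip_ranges <- if (!is.null(config$tip_ranges)) unlist(config$tip_ranges)
    else {
      tab <- utils::read.table(.require_file(config$ranges_file, "tip ranges"),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      setNames(tab[[2]], tab[[1]])
    }
  geo <- .geo_from_config(config$geography)
  root_prior <- if (is.null(config$root_prior)) "uniform" else config$root_prior
  bounds <- if (is.null(config$bounds)) c(1e-6, 10) else unlist(config$bounds)
  fit <- fit_dec(chrono, tip_ranges, geo, bounds = bounds,
                 starts = config$starts, root_prior = root_prior)
  splits <- ancestral_splits(chrono, tip_ranges, geo,
                             list(d = fit$d, e = fit$e),
                             root_prior = root_prior)
  outputs <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(config$out_dir, "node_splits.tsv")
    write_split_table(splits, f1)
    f2 <- file.path(config$out_dir, "best_splits.nwk")
    writeLines(annotate_tree_with_splits(splits, chrono), f2)
    f3 <- file.path(config$out_dir, "dec_fit.json")
    jsonlite::write_json(list(
      d = fit$d, e = fit$e, loglik = fit$loglik,
      diagnostics = fit$diagnostics,
      run = .provenance(config[!vapply(config, is.object, TRUE)])),
      f3, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    outputs <- c(f1, f2, f3)
  }
  out <- list(fit = fit, splits = splits)
  attr(out, "outputs") <- outputs
  invisible(out)
}

#' Five-number spore measurement summaries
#'
#' Summarises spore lengths, widths and the per-spore length/width ratio Q
#' in the conventional mycological form
#' `(MIN) mean-SD - mean - mean+SD (MAX)`: the absolute extremes are shown,
#' in brackets, only when they fall outside the mean +/- SD band.  SD is the
#' sample standard deviation (n - 1 denominator).
#'
#' @param length spore lengths (micrometres), positive.
#' @param width optional spore widths, positive, same order (Q is computed
#'   per spore, then summarised).
#' @param digits decimal places in the formatted strings.
#' @return object of class `"measurement_summary"` with components `length`,
#'   `width`, `q` (each: `min`, `lower`, `mean`, `upper`, `max`, `sd`, `n`,
#'   `formatted`) and a combined `formatted` string.
#' @export
summarize_measurements <- function(length, width = NULL, digits = 1) {
  if (any(length <= 0)) stop("nonpositive length measurement")
  if (!is.null(width)) {
    if (any(width <= 0)) stop("nonpositive width measurement")
    if (base::length(width) != base::length(length))
      stop("length and width must be paired per spore")
  }
  five <- function(x, dg) {
    n <- base::length(x)
    s <- if (n >= 2L) stats::sd(x) else 0
    m <- mean(x)
    out <- list(min = min(x), lower = m - s, mean = m, upper = m + s,
                max = max(x), sd = s, n = n)
    fmt <- function(v) formatC(v, format = "f", digits = dg)
    core <- paste0(fmt(out$lower), "–", fmt(out$mean), "–",
                   fmt(out$upper))
    pre <- if (out$min < out$lower - 10^(-dg) / 2)
      paste0("(", fmt(out$min), ") ") else ""
    post <- if (out$max > out$upper + 10^(-dg) / 2)
      paste0(" (", fmt(out$max), ")") else ""
    out$formatted <- paste0(pre, core, post)
    out
  }
  res <- list(length = five(length, digits))
  if (!is.null(width)) {
    res$width <- five(width, digits)
    res$q <- five(length / width, max(digits, 2))
    res$formatted <- paste0(res$length$formatted, " × ",
                            res$width$formatted, " µm, Q = ",
                            res$q$formatted)
  } else {
    res$formatted <- paste0(res$length$formatted, " µm")
  }
  structure(res, class = "measurement_summary")
}

#' @export
print.measurement_summary <- function(x, ...) {
  cat(x$formatted, "\n")
  invisible(x)
}
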