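#' Read a plate-count CSV
#'
#' Reads and validates a plate-count table with header
#' `plate_id,genotype,assay_type,n_toward,n_away,n_middle`. Malformed rows
#' are reported with their row numbers.
#'
#' @param path Path to the CSV.
#' @return Tibble of validated plate counts (possibly empty, with a
#'   warning).
#' @export
read_plate_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("plate_id", "genotype", "assay_type",
              "n_toward", "n_away", "n_middle")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("plate-count file lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("plate-count file '", path, "' contains no rows", call. = FALSE)
    return(tibble::as_tibble(df[needed]))
  }
  problems <- character(0)
  for (i in seq_len(nrow(df))) {
    counts <- as.numeric(df[i, c("n_toward", "n_away", "n_middle")])
    if (any(is.na(counts)) || any(counts < 0) ||
        any(abs(counts - round(counts)) > 1e-8)) {
      problems <- c(problems,
                    sprintf("row %d: counts must be nonnegative integers", i))
    } else if (sum(counts) < 1) {
      problems <- c(problems, sprintf("row %d: empty plate", i))
    }
    if (!df$assay_type[i] %in% assay_types()) {
      problems <- c(problems,
                    sprintf("row %d: unknown assay_type '%s'", i,
                            df$assay_type[i]))
    }
  }
  if (length(problems) > 0) {
    stop("invalid plate-count file '", path, "':\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  tibble::as_tibble(df[needed])
}

#' Write a plate-count (or scored) table to CSV
#'
#' @param plates Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_counts <- function(plates, path) {
  utils::write.csv(plates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read long-format fluorescence traces with stimulus epochs
#'
#' Reads a long trace CSV (`trace_id,neuron_class,genotype,stimulus,
#' time_s,F`) and an epoch CSV (`trace_id,t_onset_s,t_removal_s`), checks
#' that every trace has exactly one epoch row, a uniform time grid and a
#' valid epoch, and returns validated [fluorescence_trace()] objects.
#'
#' @param path Trace CSV path.
#' @param epochs_path Epoch CSV path.
#' @param sampling_tol Tolerance (s) on grid uniformity.
#' @return Named list of [fluorescence_trace()] objects.
#' @export
read_traces <- function(path, epochs_path, sampling_tol = 1e-6) {
  for (p in c(path, epochs_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  ep <- utils::read.csv(epochs_path, stringsAsFactors = FALSE)
  needed_tr <- c("trace_id", "neuron_class", "genotype", "stimulus",
                 "time_s", "F")
  needed_ep <- c("trace_id", "t_onset_s", "t_removal_s")
  if (length(setdiff(needed_tr, names(tr))) > 0) {
    stop("trace file lacks columns: ",
         paste(setdiff(needed_tr, names(tr)), collapse = ", "),
         call. = FALSE)
  }
  if (length(setdiff(needed_ep, names(ep))) > 0) {
    stop("epoch file lacks columns: ",
         paste(setdiff(needed_ep, names(ep)), collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(tr$trace_id)
  orphans <- setdiff(ids, ep$trace_id)
  if (length(orphans) > 0) {
    stop("traces without an epoch row: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(ids, function(id) {
    rows <- tr[tr$trace_id == id, ]
    rows <- rows[order(rows$time_s), ]
    erow <- ep[ep$trace_id == id, ]
    if (nrow(erow) != 1) {
      stop("trace '", id, "' must have exactly one epoch row", call. = FALSE)
    }
    fluorescence_trace(
      time = rows$time_s, F = rows$F,
      t_onset = erow$t_onset_s, t_removal = erow$t_removal_s,
      trace_id = id, neuron_class = rows$neuron_class[1],
      genotype = rows$genotype[1], stimulus = rows$stimulus[1],
      sampling_tol = sampling_tol
    )
  })
  names(out) <- ids
  out
}

#' Write traces to the long CSV format
#'
#' @param traces List of [fluorescence_trace()] objects.
#' @param path Trace CSV path.
#' @param epochs_path Epoch CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, epochs_path) {
  long <- dplyr::bind_rows(lapply(traces, function(x) {
    tibble::tibble(trace_id = x$trace_id, neuron_class = x$neuron_class,
                   genotype = x$genotype, stimulus = x$stimulus,
                   time_s = x$time, F = x$F)
  }))
  epochs <- dplyr::bind_rows(lapply(traces, function(x) {
    tibble::tibble(trace_id = x$trace_id, t_onset_s = x$t_onset,
                   t_removal_s = x$t_removal)
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(epochs, epochs_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quantify a set of traces
#'
#' Runs [response_metrics()] on each trace with its neuron class's default
#' windows (or an explicit override) and binds the results.
#'
#' @param traces List of [fluorescence_trace()] objects.
#' @param windows Optional [response_windows()] applied to all traces.
#' @param k_sd,cap Passed to [off_latency()].
#' @param ava_variant `"primary"` or `"ava_late"`: which default ON window
#'   to use for AVA traces when `windows` is `NULL`.
#' @return Tibble of per-trace metrics.
#' @export
quantify_traces <- function(traces, windows = NULL, k_sd = 3, cap = 40,
                            ava_variant = "primary") {
  dplyr::bind_rows(lapply(traces, function(x) {
    w <- windows
    if (is.null(w) && x$neuron_class %in% c("AWB", "ASH", "AVA", "AIB",
                                            "RIM")) {
      w <- default_windows(x$neuron_class,
                           variant = if (x$neuron_class == "AVA")
                             ava_variant else "primary")
    }
    response_metrics(x, windows = w, k_sd = k_sd, cap = cap)
  }))
}

#' Read a pipeline configuration file
#'
#' YAML configuration with any of the sections `scoring`, `quant`,
#' `stats`, `plate_sim`, `trace_sim` and a top-level `seed`; missing
#' options fall back to the package defaults documented on each function.
#'
#' @param path YAML file path.
#' @return Named list of options.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg
}

#' End-to-end synthetic report
#'
#' Runs the full synthetic pipeline: simulate plates for the three assay
#' types and both genotype presets, score them, compute group integration
#' indices, compare wild-type and mutant per-plate indices with the
#' normality-branched procedure, and write all outputs plus a run log
#' (seed and resolved options) to `out_dir`. With the same seed the
#' numeric outputs are reproducible bit for bit.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_plates Plates per genotype and assay type.
#' @param seed Integer master seed.
#' @param config Base [plate_sim_config()].
#' @param genotypes Genotype presets to simulate.
#' @return Invisibly, a list with the scored table, integration summaries
#'   and the comparison table.
#' @export
run_report <- function(out_dir, n_plates = 10, seed = 1L,
                       config = plate_sim_config(),
                       genotypes = c("wild_type", "osm5_like")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plates <- list()
  integ <- list()
  for (gi in seq_along(genotypes)) {
    g <- genotypes[gi]
    per_assay <- lapply(assay_types(), function(a) {
      simulate_plates(n_plates, a, genotype = g, config = config,
                      seed = seed + 10000L * gi +
                        1000L * match(a, assay_types()))
    })
    names(per_assay) <- assay_types()
    plates[[g]] <- dplyr::bind_rows(per_assay)
    integ[[g]] <- group_integration(per_assay$attractant,
                                    per_assay$repellent,
                                    per_assay$pairing)
  }
  all_plates <- dplyr::bind_rows(plates)
  scored <- score_plates(all_plates)
  write_plate_counts(scored, file.path(out_dir, "scored_plates.csv"))

  integ_tbl <- dplyr::bind_rows(lapply(genotypes, function(g) {
    s <- integ[[g]]
    tibble::tibble(genotype = g,
                   ci_attractant = s$ci_attractant,
                   ci_repellent = s$ci_repellent,
                   ci_pairing = s$ci_pairing,
                   integration_index_pct = s$integration_index_pct,
                   n_pairing_plates = length(s$per_plate_values))
  }))
  utils::write.csv(integ_tbl, file.path(out_dir, "integration_summary.csv"),
                   row.names = FALSE, quote = FALSE)

  cmp <- NULL
  if (length(genotypes) >= 2) {
    cmp <- compare_two(integ[[genotypes[1]]]$per_plate_values,
                       integ[[genotypes[2]]]$per_plate_values)
    cmp$comparison <- paste(genotypes[1], "vs", genotypes[2],
                            "(integration index)")
    utils::write.csv(cmp, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  log_lines <- c(
    "olfint run_report",
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("seed: ", seed),
    paste0("n_plates: ", n_plates),
    paste0("genotypes: ", paste(genotypes, collapse = ", ")),
    paste0("config: ", paste(names(unclass(config)),
                             vapply(unclass(config), function(v)
                               paste(format(v), collapse = ","),
                               character(1)),
                             sep = "=", collapse = "; "))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(scored = scored, integration = integ_tbl,
                 comparisons = cmp))
}
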