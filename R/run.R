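# High-level runners binding the pipeline stages: read -> correct ->
# detect -> analyse -> write.  These back the command-line front end in
# inst/cli/lta.R; all outputs are plain CSV/JSON/DOT files plus a config
# echo for provenance.

#' Assemble and validate a run configuration
#'
#' @param input Path to the input CSV, or an \code{lta_table}.
#' @param network Preset name or \code{compartment_network}.
#' @param control,experimental Phenotype labels.
#' @param layout CSV layout (\code{"wide"}/\code{"long"}).
#' @param mode Optional ionisation-mode filter (\code{"positive"} /
#'   \code{"negative"}); modes are analysed separately.
#' @param io_config Column-name mapping passed to [read_table()].
#' @param min_fraction Presence threshold (default 0.5).
#' @param alpha,correction Abundance significance settings.
#' @param p_method,draws,seed Jaccard p-value settings.
#' @param include_a Include ubiquitous variables in axis comparisons?
#' @param out_dir Output directory (created if needed).
#' @return A validated \code{run_config} list.
#' @export
run_config <- function(input, network, control, experimental,
                       layout = "wide", mode = NULL, io_config = list(),
                       min_fraction = 0.5, alpha = 0.05,
                       correction = "sqrt", p_method = "exact",
                       draws = 10000L, seed = 1L, include_a = TRUE,
                       out_dir = tempfile("lta_run_")) {
  if (is.character(network)) network <- preset_network(network)
  cfg <- list(input = input, network = network, control = control,
              experimental = experimental, layout = layout, mode = mode,
              io_config = io_config, min_fraction = min_fraction,
              alpha = alpha, correction = correction, p_method = p_method,
              draws = as.integer(draws), seed = as.integer(seed),
              include_a = include_a, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

# Load, mode-filter and signal-correct the input table; validate phenotypes
# and compartments before any computation.
.load_table <- function(config) {
  table <- if (inherits(config$input, "lta_table")) config$input else
    read_table(config$input, layout = config$layout,
               config = config$io_config)
  if (!is.null(config$mode)) {
    keep <- table$samples$mode == config$mode
    if (!any(keep)) stop("no samples in mode '", config$mode, "'")
    table <- lta_table(table$values[keep, , drop = FALSE],
                       table$samples[keep, , drop = FALSE],
                       internal_standards = table$internal_standards,
                       corrected = table$corrected)
  }
  for (ph in c(config$control, config$experimental)) {
    if (!ph %in% table$samples$phenotype) {
      stop("phenotype label '", ph, "' not found in the data")
    }
  }
  extra <- setdiff(unique(table$samples$compartment), config$network$nodes)
  if (length(extra) > 0L) {
    stop("data/network mismatch: compartments not in the network: ",
         paste(extra, collapse = ", "))
  }
  if (!table$corrected) table <- signal_correct(table)
  table
}

.echo_config <- function(config, log_path) {
  ser <- config
  ser$network <- list(nodes = config$network$nodes,
                      edges = config$network$edges,
                      origin = config$network$origin,
                      hub = config$network$hub,
                      termini = config$network$termini)
  ser$input <- if (is.character(config$input)) config$input else
    "<in-memory table>"
  jsonlite::write_json(unclass(ser), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  writeLines(c(
    paste("lipidtraffic run:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("control:", config$control, " experimental:", config$experimental),
    paste("axes:", paste(axes(config$network)$label, collapse = ", ")),
    paste("presence threshold:", config$min_fraction),
    paste("alpha:", config$alpha, " correction:", config$correction),
    paste("p method:", config$p_method, " seed:", config$seed)
  ), log_path)
}

#' Run the Switch Analysis end to end
#'
#' Writes \code{switch_categories.csv} (variable x phenotype x category),
#' \code{axis_comparisons.csv} (counts, J, p per axis),
#' \code{switch_counts.csv}, routing graphs for any re-routed variables
#' between every hub-sharing axis pair (\code{routing.dot} /
#' \code{routing.graphml}), a config echo and a log file.
#'
#' @param config A \code{run_config}.
#' @return The \code{switch_report}, invisibly; file outputs under
#'   \code{config$out_dir}.
#' @export
run_switch <- function(config) {
  stopifnot(inherits(config, "run_config"))
  table <- .load_table(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "switch.log")
  .echo_config(config, log_path)

  presence <- detect_presence(table, config$network$nodes,
                              min_fraction = config$min_fraction)
  report <- switch_report(presence, config$network, config$control,
                          config$experimental,
                          include_a = config$include_a,
                          p_method = config$p_method,
                          draws = config$draws, seed = config$seed)

  utils::write.csv(switch_report_table(report),
                   file.path(config$out_dir, "switch_categories.csv"),
                   row.names = FALSE)
  utils::write.csv(report$comparisons,
                   file.path(config$out_dir, "axis_comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(phenotype = rownames(report$counts),
                              report$counts, check.names = FALSE),
                   file.path(config$out_dir, "switch_counts.csv"),
                   row.names = FALSE)

  ax <- axes(config$network)
  rerouted <- character(0)
  for (i in seq_len(nrow(ax))) for (j in seq_len(nrow(ax))) {
    if (i == j) next
    shared <- intersect(c(ax$from[i], ax$to[i]), c(ax$from[j], ax$to[j]))
    if (length(shared) == 0L) next
    rr <- find_rerouted(report, ax$label[i], ax$label[j])
    if (length(rr) > 0L) {
      rerouted <- union(rerouted, rr)
      cat("re-routed ", ax$label[i], " -> ", ax$label[j], ": ",
          paste(rr, collapse = ", "), "\n", sep = "",
          file = log_path, append = TRUE)
    }
  }
  if (length(rerouted) > 0L) {
    diagram <- routing_diagram(report, rerouted)
    write_routing(diagram, file.path(config$out_dir, "routing.dot"), "dot")
    write_routing(diagram, file.path(config$out_dir, "routing.graphml"),
                  "graphml")
    utils::write.csv(diagram$edges,
                     file.path(config$out_dir, "routing_edges.csv"),
                     row.names = FALSE)
  }
  invisible(report)
}

#' Run the Abundance Analysis end to end
#'
#' Writes \code{abundance_report.csv} (one row per variable x compartment)
#' and \code{enfc_matrix.csv} (variables x compartments, for radar-style
#' plotting), plus a config echo and a log recording the corrected
#' threshold used.
#'
#' @param config A \code{run_config}.
#' @return The \code{abundance_report}, invisibly.
#' @export
run_abundance <- function(config) {
  stopifnot(inherits(config, "run_config"))
  table <- .load_table(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "abundance.log")
  .echo_config(config, log_path)

  report <- abundance_report(table, config$network, config$control,
                             config$experimental, alpha = config$alpha,
                             correction = config$correction)
  cat("corrected threshold: ", signif(attr(report, "threshold"), 2),
      " (", length(lta_variables(table)), " variables)\n", sep = "",
      file = log_path, append = TRUE)

  utils::write.csv(as.data.frame(report),
                   file.path(config$out_dir, "abundance_report.csv"),
                   row.names = FALSE)
  m <- enfc_matrix(report)
  utils::write.csv(data.frame(variable = rownames(m), m,
                              check.names = FALSE),
                   file.path(config$out_dir, "enfc_matrix.csv"),
                   row.names = FALSE)
  invisible(report)
}
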