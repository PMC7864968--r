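# The binary Switch Analysis.
#
# Per phenotype, lipid variables are partitioned by where they are detected:
#   A - present in every compartment of the network (ubiquitous);
#   B - present in both endpoints of an axis but not ubiquitous, keyed by
#       the directional axis label (e.g. "LS");
#   U - present in a compartment and in none of its neighbours.
# Phenotypes are then compared axis by axis with Jaccard-Tanimoto
# statistics, and variables re-routed between axes are identified.

#' Categorise present variables into A, B and U sets for one phenotype
#'
#' A is the intersection of the per-compartment presence sets over all
#' compartments.  B for an axis is the intersection of the two endpoint
#' sets minus A.  U for a compartment is its presence set minus everything
#' shared with any neighbour; co-presence in non-adjacent compartments does
#' not remove a variable from U.
#'
#' @param presence A \code{presence_map} from [detect_presence()].
#' @param network A \code{compartment_network}.
#' @param phenotype Phenotype label to categorise.
#' @param pooled Use pooled (either-phenotype) presence sets instead of the
#'   per-phenotype sets?  Default \code{FALSE}: the switch sets compare
#'   phenotypes, so presence is evaluated within each phenotype.
#' @return List with \code{A} (character vector), \code{B} (named list,
#'   axis label -> character vector), \code{U} (named list, compartment ->
#'   character vector) and \code{present} (the per-compartment sets used).
#' @export
categorize <- function(presence, network, phenotype, pooled = FALSE) {
  stopifnot(inherits(presence, "presence_map"),
            inherits(network, "compartment_network"))
  comps <- network$nodes
  sets <- if (pooled) {
    missing <- setdiff(comps, names(presence$pooled))
    if (length(missing) > 0L) {
      stop("compartments missing from presence map: ",
           paste(missing, collapse = ", "))
    }
    presence$pooled[comps]
  } else {
    .presence_sets(presence, phenotype, comps)
  }

  A <- sort(Reduce(intersect, sets))
  ax <- axes(network)
  B <- stats::setNames(vector("list", nrow(ax)), ax$label)
  for (i in seq_len(nrow(ax))) {
    B[[ax$label[i]]] <- sort(setdiff(intersect(sets[[ax$from[i]]],
                                               sets[[ax$to[i]]]), A))
  }
  U <- stats::setNames(vector("list", length(comps)), comps)
  for (cc in comps) {
    nb <- neighbours_of(network, cc)
    U[[cc]] <- sort(setdiff(sets[[cc]], unique(unlist(sets[nb]))))
  }
  list(A = A, B = B, U = U, present = sets, phenotype = phenotype)
}

#' Full switch report comparing two phenotypes
#'
#' Categorises both phenotypes and compares every axis of the network with
#' Jaccard-Tanimoto statistics.
#'
#' @param presence A \code{presence_map}.
#' @param network A \code{compartment_network}.
#' @param control,experimental Phenotype labels.
#' @param include_a Count ubiquitous (A-type) variables as travelling every
#'   axis when comparing axes (default \code{TRUE}; they demonstrably reach
#'   both endpoints).  With \code{FALSE} only B-type variables are compared.
#' @param p_method,draws,seed Passed to [jaccard_pvalue()].
#' @return A \code{switch_report}: list with \code{network},
#'   \code{control}, \code{experimental}, per-phenotype categorisations
#'   (\code{categories}), \code{comparisons} (data.frame: axis, counts, J,
#'   p) and \code{counts} (per-phenotype A/B/U tallies for pie-chart style
#'   summaries).
#' @export
switch_report <- function(presence, network, control, experimental,
                          include_a = TRUE,
                          p_method = c("exact", "montecarlo"),
                          draws = 10000L, seed = NULL) {
  p_method <- match.arg(p_method)
  cats <- stats::setNames(
    lapply(c(control, experimental), function(ph)
      categorize(presence, network, ph)),
    c(control, experimental))

  report <- structure(
    list(network = network, control = control, experimental = experimental,
         categories = cats, include_a = include_a,
         p_method = p_method, draws = draws, seed = seed),
    class = "switch_report"
  )
  ax <- axes(network)
  comp_rows <- lapply(ax$label, function(lab)
    as.data.frame(compare_axis(report, lab)))
  report$comparisons <- do.call(rbind, comp_rows)

  tally <- function(cat) {
    c(A = length(cat$A),
      B = length(unique(unlist(cat$B))),
      U = length(unique(unlist(cat$U))))
  }
  report$counts <- t(vapply(cats, tally, numeric(3)))
  report
}

#' @export
print.switch_report <- function(x, ...) {
  cat("<switch_report> ", x$control, " vs ", x$experimental, " on ",
      nrow(axes(x$network)), " axes\n", sep = "")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

# Variables travelling an axis for one phenotype: B-type on the axis,
# plus the ubiquitous A set unless include_a is FALSE.
.axis_members <- function(report, phenotype, axis_label) {
  cat <- report$categories[[phenotype]]
  if (is.null(cat)) stop("phenotype '", phenotype, "' not in report")
  if (!axis_label %in% names(cat$B)) {
    stop("unknown axis '", axis_label, "'; axes: ",
         paste(names(cat$B), collapse = ", "))
  }
  members <- cat$B[[axis_label]]
  if (report$include_a) members <- union(cat$A, members)
  sort(members)
}

#' Compare one axis between the two phenotypes
#'
#' The two lists compared are the variables travelling the axis in each
#' phenotype (see \code{include_a} in [switch_report()]).  The universe for
#' the resampling null is the union of the two lists.
#'
#' @param report A \code{switch_report}.
#' @param axis_label Axis label, e.g. \code{"LS"}.
#' @return List \code{axis}, \code{n_control}, \code{n_experimental},
#'   \code{J}, \code{p}.
#' @export
compare_axis <- function(report, axis_label) {
  stopifnot(inherits(report, "switch_report"))
  xs <- .axis_members(report, report$control, axis_label)
  ys <- .axis_members(report, report$experimental, axis_label)
  if (length(xs) == 0L && length(ys) == 0L) {
    J <- NA_real_; p <- NA_real_
  } else {
    J <- jaccard(xs, ys)
    p <- jaccard_pvalue(xs, ys, method = report$p_method,
                        draws = report$draws, seed = report$seed)
  }
  list(axis = axis_label, n_control = length(xs),
       n_experimental = length(ys), J = J, p = p)
}

#' Variables re-routed from one axis to another between phenotypes
#'
#' A variable is re-routed when it travels \code{from_axis} in the control
#' phenotype but not in the experimental one, and travels \code{to_axis} in
#' the experimental phenotype but not in the control.  The two axes must
#' share an endpoint (the hub through which traffic is diverted).
#'
#' @param report A \code{switch_report}.
#' @param from_axis,to_axis Axis labels.
#' @return Character vector of re-routed variable names (possibly empty).
#' @export
find_rerouted <- function(report, from_axis, to_axis) {
  stopifnot(inherits(report, "switch_report"))
  ax <- axes(report$network)
  ends <- function(lab) {
    i <- match(lab, ax$label)
    if (is.na(i)) stop("unknown axis '", lab, "'")
    c(ax$from[i], ax$to[i])
  }
  if (length(intersect(ends(from_axis), ends(to_axis))) == 0L) {
    stop("axes '", from_axis, "' and '", to_axis,
         "' share no endpoint; re-routing requires a common hub")
  }
  ctrl <- report$control; expt <- report$experimental
  from_ctrl <- .axis_members(report, ctrl, from_axis)
  from_expt <- .axis_members(report, expt, from_axis)
  to_ctrl <- .axis_members(report, ctrl, to_axis)
  to_expt <- .axis_members(report, expt, to_axis)
  sort(setdiff(intersect(from_ctrl, setdiff(to_expt, to_ctrl)),
               from_expt))
}

#' Routing diagram for a set of variables
#'
#' For each phenotype, lists the axes each variable travels (present at
#' both endpoints), in the style of a wiring diagram.
#'
#' @param report A \code{switch_report}.
#' @param variables Character vector of variable names known to the report.
#' @return A \code{routing_diagram}: list with \code{edges} (data.frame:
#'   phenotype, variable, axis, from, to) and \code{graph} (an igraph
#'   multigraph over compartments with edge attributes \code{variable} and
#'   \code{phenotype}).
#' @export
routing_diagram <- function(report, variables) {
  stopifnot(inherits(report, "switch_report"))
  all_vars <- unique(unlist(lapply(report$categories,
                                   function(cat) unlist(cat$present))))
  unknown <- setdiff(variables, all_vars)
  if (length(unknown) > 0L) {
    stop("variables unknown to the report: ",
         paste(unknown, collapse = ", "))
  }
  ax <- axes(report$network)
  rows <- list()
  for (ph in names(report$categories)) {
    for (i in seq_len(nrow(ax))) {
      members <- intersect(variables,
                           .axis_members(report, ph, ax$label[i]))
      if (length(members) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          phenotype = ph, variable = members, axis = ax$label[i],
          from = ax$from[i], to = ax$to[i], stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(phenotype = character(0), variable = character(0),
               axis = character(0), from = character(0), to = character(0))
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "variable", "phenotype", "axis")],
    directed = FALSE,
    vertices = data.frame(name = report$network$nodes))
  structure(list(edges = edges, graph = g), class = "routing_diagram")
}

#' Write a routing diagram as DOT or GraphML
#' @param diagram A \code{routing_diagram}.
#' @param path Output file path.
#' @param format \code{"dot"} or \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
write_routing <- function(diagram, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  igraph::write_graph(diagram$graph, path, format = format)
  invisible(path)
}

#' Switch report as a tidy data.frame
#'
#' One row per (phenotype, category, variable); B rows carry the axis
#' label, U rows the compartment.
#'
#' @param report A \code{switch_report}.
#' @return data.frame with columns \code{phenotype}, \code{category},
#'   \code{location}, \code{variable}.
#' @export
switch_report_table <- function(report) {
  rows <- list()
  add <- function(ph, category, location, vars) {
    if (length(vars) > 0L) {
      rows[[length(rows) + 1L]] <<- data.frame(
        phenotype = ph, category = category, location = location,
        variable = vars, stringsAsFactors = FALSE)
    }
  }
  for (ph in names(report$categories)) {
    cat <- report$categories[[ph]]
    add(ph, "A", "all", cat$A)
    for (lab in names(cat$B)) add(ph, "B", lab, cat$B[[lab]])
    for (cc in names(cat$U)) add(ph, "U", cc, cat$U[[cc]])
  }
  if (length(rows) == 0L) {
    return(data.frame(phenotype = character(0), category = character(0),
                      location = character(0), variable = character(0)))
  }
  do.call(rbind, rows)
}
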