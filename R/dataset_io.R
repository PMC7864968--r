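# Sample-by-lipid abundance tables: construction, CSV input, signal
# correction to per-mille relative abundance, and the detection rule.

#' Construct an abundance table
#'
#' The central data container: a numeric matrix of signals (rows = samples,
#' columns = lipid variables) together with per-sample metadata.
#'
#' @param values Non-negative numeric matrix, samples x variables, with
#'   column names.
#' @param samples data.frame with one row per row of \code{values}:
#'   \code{sample_id}, \code{compartment}, \code{phenotype} and optionally
#'   \code{generation}, \code{mode} (\code{"positive"}/\code{"negative"})
#'   and \code{petrol_washed}.
#' @param internal_standards Character vector of column names that are
#'   internal standards (excluded from the signal-correction denominator
#'   and dropped from the analysis set).
#' @param corrected Logical: are the values already per-mille relative
#'   abundances?
#' @return An object of class \code{lta_table}.
#' @export
lta_table <- function(values, samples, internal_standards = character(0),
                      corrected = FALSE) {
  values <- as.matrix(values)
  stopifnot(
    is.numeric(values), !is.null(colnames(values)),
    nrow(values) == nrow(samples),
    all(c("sample_id", "compartment", "phenotype") %in% names(samples))
  )
  if (anyNA(values)) stop("values contain NA; encode non-detection as 0")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop("negative value at sample '", samples$sample_id[neg[1, 1]],
         "', variable '", colnames(values)[neg[1, 2]], "'")
  }
  if (anyNA(samples$compartment) || anyNA(samples$phenotype) ||
      anyNA(samples$sample_id)) {
    stop("missing sample metadata (sample_id/compartment/phenotype)")
  }
  if (!all(internal_standards %in% colnames(values))) {
    stop("internal standards absent from table: ",
         paste(setdiff(internal_standards, colnames(values)), collapse = ", "))
  }
  if (!"mode" %in% names(samples)) samples$mode <- "positive"
  rownames(values) <- samples$sample_id
  structure(
    list(values = values, samples = as.data.frame(samples),
         internal_standards = internal_standards, corrected = corrected),
    class = "lta_table"
  )
}

#' @export
print.lta_table <- function(x, ...) {
  cat("<lta_table> ", nrow(x$values), " samples x ", ncol(x$values),
      " lipid variables", if (x$corrected) " (per-mille corrected)", "\n",
      sep = "")
  cat("  compartments: ", paste(unique(x$samples$compartment), collapse = ", "),
      "\n  phenotypes:   ", paste(unique(x$samples$phenotype), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Variable names of an abundance table
#' @param table An \code{lta_table}.
#' @param include_standards Keep internal-standard columns?
#' @return Character vector.
#' @export
lta_variables <- function(table, include_standards = FALSE) {
  v <- colnames(table$values)
  if (!include_standards) v <- setdiff(v, table$internal_standards)
  v
}

#' Read an abundance table from CSV
#'
#' Wide layout: one row per sample, metadata columns followed by one column
#' per lipid variable.  Long layout: one row per (sample, variable) with a
#' value column; pivoted to wide on read.
#'
#' @param path CSV file path.
#' @param layout \code{"wide"} or \code{"long"}.
#' @param config Named list mapping metadata roles to column names.
#'   Recognised roles: \code{sample_id}, \code{compartment},
#'   \code{phenotype}, \code{generation}, \code{mode}, \code{petrol_washed},
#'   and for long layout \code{variable}, \code{value}.  Defaults are the
#'   role names themselves.  \code{internal_standards}: character vector of
#'   variable names to treat as internal standards.
#' @return An \code{lta_table} (uncorrected).
#' @export
read_table <- function(path, layout = c("wide", "long"), config = list()) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- function(role) if (!is.null(config[[role]])) config[[role]] else role
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)

  meta_roles <- c("sample_id", "compartment", "phenotype", "generation",
                  "mode", "petrol_washed")
  meta_cols <- vapply(meta_roles, cols, character(1))
  required <- meta_cols[c("sample_id", "compartment", "phenotype")]
  if (layout == "long") required <- c(required, cols("variable"), cols("value"))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("declared metadata columns absent from file: ",
         paste(missing, collapse = ", "))
  }

  present_meta <- meta_cols[meta_cols %in% names(df)]
  if (layout == "wide") {
    samples <- df[, present_meta, drop = FALSE]
    names(samples) <- names(present_meta)
    var_cols <- setdiff(names(df), present_meta)
    values <- as.matrix(df[, var_cols, drop = FALSE])
  } else {
    vcol <- cols("variable"); acol <- cols("value")
    key <- paste(df[[cols("sample_id")]], df[[vcol]], sep = "\r")
    if (anyDuplicated(key) > 0L) {
      d <- key[duplicated(key)][1]
      stop("duplicate (sample, variable) cell in long layout: ",
           gsub("\r", " / ", d))
    }
    sample_ids <- unique(df[[cols("sample_id")]])
    vars <- unique(df[[vcol]])
    values <- matrix(0, nrow = length(sample_ids), ncol = length(vars),
                     dimnames = list(sample_ids, vars))
    values[cbind(match(df[[cols("sample_id")]], sample_ids),
                 match(df[[vcol]], vars))] <- df[[acol]]
    meta <- df[!duplicated(df[[cols("sample_id")]]), present_meta, drop = FALSE]
    names(meta) <- names(present_meta)
    samples <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  }
  if ("petrol_washed" %in% names(samples)) {
    samples$petrol_washed <- as.logical(samples$petrol_washed)
  }
  rownames(samples) <- NULL
  lta_table(values, samples,
            internal_standards = as.character(config$internal_standards %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an abundance table to wide CSV
#' @param table An \code{lta_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_table_csv <- function(table, path) {
  out <- cbind(table$samples, as.data.frame(table$values, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Signal-correct a table to per-mille relative abundance
#'
#' Each sample's signals are divided by that sample's total signal excluding
#' internal standards, and expressed per mille: corrected rows sum to 1000
#' over the analyte columns.  Internal-standard columns are dropped from the
#' analysis set (kept in the \code{"standards"} attribute for provenance).
#' Idempotent on already-corrected rows.
#'
#' @param table An \code{lta_table}.
#' @return A corrected \code{lta_table}.
#' @export
signal_correct <- function(table) {
  stopifnot(inherits(table, "lta_table"))
  analytes <- lta_variables(table)
  v <- table$values[, analytes, drop = FALSE]
  totals <- rowSums(v)
  if (any(totals <= 0)) {
    bad <- table$samples$sample_id[which(totals <= 0)[1]]
    stop("sample '", bad, "' has zero total signal over analytes")
  }
  corrected <- sweep(v, 1, totals, "/") * 1000
  out <- lta_table(corrected, table$samples, corrected = TRUE)
  attr(out, "standards") <- table$values[, table$internal_standards,
                                         drop = FALSE]
  out
}

#' Apply the detection rule and build a presence map
#'
#' A variable is deemed present in a compartment for a phenotype group when
#' its signal is strictly positive in at least 50\% of that group's samples
#' in that compartment (evaluated on the exact fraction; 2 of 4 counts, 2 of
#' 5 does not).  Pooled presence (used for overall detection) requires the
#' rule to hold in at least one phenotype group.
#'
#' @param table An \code{lta_table}.
#' @param network_compartments Character vector of compartments expected by
#'   the network; every sample's compartment must be among them.
#' @param min_fraction Detection fraction threshold (default 0.5).
#' @return A \code{presence_map}: list with \code{phenotypes},
#'   \code{compartments}, \code{entries} (per-phenotype: compartment ->
#'   character vector of present variables), \code{pooled} (compartment ->
#'   variables present in either phenotype), \code{sample_counts}
#'   (compartment x phenotype matrix) and \code{no_data} (data.frame of
#'   (compartment, phenotype) pairs with zero samples, flagged rather than
#'   silently empty).
#' @export
detect_presence <- function(table, network_compartments,
                            min_fraction = 0.5) {
  stopifnot(inherits(table, "lta_table"))
  comp <- table$samples$compartment
  if (!all(comp %in% network_compartments)) {
    stop("samples in compartments outside the network: ",
         paste(setdiff(unique(comp), network_compartments), collapse = ", "))
  }
  phenotypes <- unique(table$samples$phenotype)
  vars <- lta_variables(table)
  v <- table$values[, vars, drop = FALSE] > 0

  entries <- stats::setNames(vector("list", length(phenotypes)), phenotypes)
  counts <- matrix(0L, nrow = length(network_compartments),
                   ncol = length(phenotypes),
                   dimnames = list(network_compartments, phenotypes))
  no_data <- data.frame(compartment = character(0), phenotype = character(0))

  for (ph in phenotypes) {
    per_comp <- stats::setNames(vector("list", length(network_compartments)),
                                network_compartments)
    for (cc in network_compartments) {
      rows <- which(comp == cc & table$samples$phenotype == ph)
      counts[cc, ph] <- length(rows)
      if (length(rows) == 0L) {
        per_comp[[cc]] <- NA  # absent-by-no-data, flagged below
        no_data <- rbind(no_data,
                         data.frame(compartment = cc, phenotype = ph))
        next
      }
      frac <- colMeans(v[rows, , drop = FALSE])
      per_comp[[cc]] <- vars[frac >= min_fraction]
    }
    entries[[ph]] <- per_comp
  }

  pooled <- stats::setNames(vector("list", length(network_compartments)),
                            network_compartments)
  for (cc in network_compartments) {
    sets <- lapply(entries, function(e) e[[cc]])
    sets <- sets[!vapply(sets, function(s) length(s) == 1L && is.na(s[1]),
                         logical(1))]
    pooled[[cc]] <- if (length(sets) == 0L) character(0) else
      sort(unique(unlist(sets)))
  }

  structure(
    list(phenotypes = phenotypes, compartments = network_compartments,
         entries = entries, pooled = pooled, sample_counts = counts,
         no_data = no_data, variables = vars),
    class = "presence_map"
  )
}

#' @export
print.presence_map <- function(x, ...) {
  cat("<presence_map> ", length(x$compartments), " compartments x ",
      length(x$phenotypes), " phenotypes, ", length(x$variables),
      " variables\n", sep = "")
  if (nrow(x$no_data) > 0L) {
    cat("  no-data entries: ",
        paste(x$no_data$compartment, x$no_data$phenotype, sep = "/",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Internal: presence sets for one phenotype, erroring on no-data entries.
.presence_sets <- function(presence, phenotype, compartments) {
  if (!phenotype %in% presence$phenotypes) {
    stop("phenotype '", phenotype, "' not in presence map")
  }
  sets <- presence$entries[[phenotype]][compartments]
  for (cc in compartments) {
    s <- sets[[cc]]
    if (is.null(s)) stop("compartment '", cc, "' missing from presence map")
    if (length(s) == 1L && is.na(s[1])) {
      stop("no samples for compartment '", cc, "', phenotype '", phenotype,
           "' (absent-by-no-data)")
    }
  }
  sets
}
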