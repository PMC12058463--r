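# Core tables and their delimited-text readers/writers.
#
# Dialect: UTF-8, comma-delimited, mandatory header. Multi-valued nominal
# trait cells use ";" between category codes. An empty cell means the trait is
# structurally inapplicable for the taxon; the token "NA" means unknown but
# applicable. Both are scored identically by the dissimilarity weights.

#' Construct and validate a species-by-traits table
#'
#' @param df A data.frame with columns `species_id`, `endemic` (logical),
#'   optional `herbaceous` and `gymnosperm` flags, and one column per trait in
#'   `schema`. Nominal trait columns are list-columns of integer code vectors
#'   (length 0 = missing) or character cells with ";"-separated codes;
#'   interval/ordinal columns are numeric with `NA` for missing.
#' @param schema Named list of trait definitions; see [default_trait_schema()].
#' @return A validated `trait_table` (a data.frame with list-columns for
#'   nominal traits and the schema stored as an attribute).
#' @export
trait_table <- function(df, schema = default_trait_schema()) {
  fdg_assert(is.data.frame(df), "trait table must be a data.frame",
             "fdg_schema_error")
  fdg_assert(all(c("species_id", "endemic") %in% names(df)),
             "trait table needs 'species_id' and 'endemic' columns",
             "fdg_schema_error")
  df$species_id <- as.character(df$species_id)
  dup <- unique(df$species_id[duplicated(df$species_id)])
  fdg_assert(length(dup) == 0,
             sprintf("duplicate species_id: %s",
                     paste(utils::head(dup, 5), collapse = ", ")),
             "fdg_schema_error")
  df$endemic <- parse_logical(df$endemic, "endemic")
  for (fl in c("herbaceous", "gymnosperm")) {
    if (fl %in% names(df)) df[[fl]] <- parse_logical(df[[fl]], fl)
  }
  missing_traits <- setdiff(names(schema), names(df))
  fdg_assert(length(missing_traits) == 0,
             sprintf("trait columns missing: %s",
                     paste(missing_traits, collapse = ", ")),
             "fdg_schema_error")

  for (tn in names(schema)) {
    def <- schema[[tn]]
    if (def$kind == "nominal") {
      df[[tn]] <- parse_nominal_column(df[[tn]], def, df$species_id)
    } else {
      df[[tn]] <- parse_numeric_trait(df[[tn]], def, df$species_id)
    }
  }
  check_structural_missingness(df, schema)
  structure(df, schema = schema, class = c("trait_table", "data.frame"))
}

parse_logical <- function(x, what) {
  if (is.logical(x)) return(x)
  out <- as.logical(toupper(trimws(as.character(x))))
  num <- suppressWarnings(as.numeric(as.character(x)))
  out[is.na(out) & !is.na(num)] <- num[is.na(out) & !is.na(num)] != 0
  fdg_assert(!anyNA(out), sprintf("column '%s' must be logical (TRUE/FALSE)", what),
             "fdg_schema_error")
  out
}

parse_nominal_column <- function(col, def, ids) {
  cells <- if (is.list(col)) col else {
    lapply(as.character(col), function(s) {
      s <- trimws(s)
      if (is.na(s) || s == "" || toupper(s) == "NA") return(integer(0))
      as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  cells <- lapply(cells, function(v) sort(unique(as.integer(v[!is.na(v)]))))
  for (i in seq_along(cells)) {
    bad <- setdiff(cells[[i]], def$codes)
    fdg_assert(length(bad) == 0,
               sprintf("species '%s', trait '%s': code %s not in allowed set %d-%d",
                       ids[i], def$name, paste(bad, collapse = ","),
                       min(def$codes), max(def$codes)),
               "fdg_schema_error")
  }
  I(cells)
}

parse_numeric_trait <- function(col, def, ids) {
  if (is.list(col)) col <- vapply(col, function(v) {
    if (length(v) == 0) NA_real_ else as.numeric(v[1])
  }, 0)
  ch <- trimws(as.character(col))
  out <- suppressWarnings(as.numeric(ifelse(ch == "" | toupper(ch) == "NA", NA, ch)))
  bad <- which(!is.na(out) & (out < min(def$codes) | out > max(def$codes)))
  fdg_assert(length(bad) == 0,
             sprintf("species '%s', trait '%s': value %s outside allowed range %d-%d",
                     ids[bad[1]], def$name, out[bad[1]],
                     min(def$codes), max(def$codes)),
             "fdg_schema_error")
  out
}

# A trait value where the applicability rule says "structurally missing" must
# indeed be missing; raised as a schema error rather than silently dropped.
check_structural_missingness <- function(df, schema) {
  for (tn in names(schema)) {
    def <- schema[[tn]]
    if (is.na(def$not_applicable) || !def$not_applicable %in% names(df)) next
    flagged <- which(df[[def$not_applicable]])
    if (length(flagged) == 0) next
    has_val <- if (def$kind == "nominal") {
      vapply(df[[tn]][flagged], length, 0L) > 0
    } else !is.na(df[[tn]][flagged])
    fdg_assert(!any(has_val),
               sprintf("trait '%s' scored for %s taxon '%s' where it is structurally inapplicable",
                       tn, def$not_applicable,
                       df$species_id[flagged[which(has_val)[1]]]),
               "fdg_schema_error")
  }
  invisible(TRUE)
}

#' Read a species-by-traits table from CSV
#'
#' @param path Path to a UTF-8 comma-delimited file with a header row; one row
#'   per species. Multi-valued nominal cells use ";" between codes; an empty
#'   cell marks structural missingness, the token "NA" an unknown value.
#' @param schema Trait schema, see [default_trait_schema()].
#' @return A validated [trait_table()].
#' @export
read_trait_table <- function(path, schema = default_trait_schema()) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  trait_table(df, schema)
}

#' Construct and validate a plot-by-species cover matrix
#'
#' Cover codes follow the 9-point Westhoff & van der Maarel cover-abundance
#' scale: present species carry integer codes 1-9, absences are 0.
#'
#' @param m Integer matrix, plots in rows (rownames = plot ids), species in
#'   columns (colnames = species ids).
#' @param traits Optional [trait_table()]; if given, every species id must
#'   resolve in it.
#' @return A validated `abundance_matrix`.
#' @export
abundance_matrix <- function(m, traits = NULL) {
  fdg_assert(is.matrix(m) && !is.null(rownames(m)) && !is.null(colnames(m)),
             "abundance matrix needs row (plot) and column (species) names",
             "fdg_value_error")
  storage.mode(m) <- "integer"
  fdg_assert(!anyNA(m), "abundance matrix contains non-integer or missing cover",
             "fdg_value_error")
  fdg_assert(all(m >= 0L & m <= 9L),
             sprintf("cover codes must be 0 (absent) or 1-9; found %d",
                     m[which(m < 0L | m > 9L)[1]]),
             "fdg_value_error")
  empty <- rownames(m)[rowSums(m > 0L) == 0L]
  fdg_assert(length(empty) == 0,
             sprintf("plots with no present species: %s",
                     paste(utils::head(empty, 5), collapse = ", ")),
             "fdg_value_error")
  if (!is.null(traits)) {
    unknown <- setdiff(colnames(m), traits$species_id)
    fdg_assert(length(unknown) == 0,
               sprintf("species absent from trait table: %s",
                       paste(utils::head(unknown, 5), collapse = ", ")),
               "fdg_value_error")
  }
  structure(m, class = c("abundance_matrix", class(matrix())))
}

#' Read a plot-by-species cover matrix from CSV
#'
#' Accepts either wide format (first column `plot_id`, one column per species)
#' or long format (columns `plot_id`, `species_id`, `cover`).
#'
#' @inheritParams abundance_matrix
#' @param path CSV path.
#' @return A validated [abundance_matrix()].
#' @export
read_plot_matrix <- function(path, traits = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (setequal(names(df), c("plot_id", "species_id", "cover"))) {
    plots <- unique(as.character(df$plot_id))
    sp <- unique(as.character(df$species_id))
    m <- matrix(0L, length(plots), length(sp), dimnames = list(plots, sp))
    cov <- suppressWarnings(as.numeric(df$cover))
    fdg_assert(!anyNA(cov) && all(cov == round(cov)),
               "long-format 'cover' must be integer", "fdg_value_error")
    m[cbind(as.character(df$plot_id), as.character(df$species_id))] <-
      as.integer(cov)
  } else {
    fdg_assert(names(df)[1] == "plot_id",
               "wide plot matrix must have 'plot_id' as its first column",
               "fdg_value_error")
    ids <- as.character(df$plot_id)
    m <- as.matrix(df[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                   dimnames = dimnames(m)))
    fdg_assert(!anyNA(num) && all(num == round(num)),
               "cover codes must be integers", "fdg_value_error")
    m <- num
    rownames(m) <- ids
  }
  abundance_matrix(m, traits)
}

#' Construct / read the per-plot environment table
#'
#' @param df Data.frame with one row per plot; columns `plot_id`, `elevation`
#'   (m, required), and optionally `tpi`, `slope` (degrees), `aspect`,
#'   `radidx` (radiation index in \[0,1\]), `twi`, `bio1`..`bio19`, `bedrock`,
#'   `habitat_type` (1-8), `x`, `y`.
#' @param plots Optional [abundance_matrix()]; plot ids must then match 1:1.
#' @return A validated `env_table` data.frame.
#' @export
env_table <- function(df, plots = NULL) {
  fdg_assert(is.data.frame(df) && all(c("plot_id", "elevation") %in% names(df)),
             "environment table needs 'plot_id' and 'elevation'",
             "fdg_schema_error")
  df$plot_id <- as.character(df$plot_id)
  num_cols <- setdiff(names(df), c("plot_id", "bedrock"))
  for (cn in num_cols) df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  fdg_assert(!anyNA(df$elevation), "missing elevation values", "fdg_value_error")
  fdg_assert(all(df$elevation >= 0), "negative elevation", "fdg_value_error")
  if ("radidx" %in% names(df)) {
    fdg_assert(all(is.na(df$radidx) | (df$radidx >= 0 & df$radidx <= 1)),
               "radiation index must lie in [0,1]", "fdg_value_error")
  }
  if ("habitat_type" %in% names(df)) {
    fdg_assert(all(is.na(df$habitat_type) | df$habitat_type %in% 1:8),
               "habitat_type codes must be 1-8", "fdg_value_error")
  }
  if (!is.null(plots)) {
    extra <- setdiff(df$plot_id, rownames(plots))
    missing <- setdiff(rownames(plots), df$plot_id)
    fdg_assert(length(extra) == 0 && length(missing) == 0,
               sprintf("plot ids do not align with abundance matrix%s%s",
                       if (length(extra)) paste0("; env-only: ",
                         paste(utils::head(extra, 5), collapse = ", ")) else "",
                       if (length(missing)) paste0("; matrix-only: ",
                         paste(utils::head(missing, 5), collapse = ", ")) else ""),
               "fdg_value_error")
  }
  structure(df, class = c("env_table", "data.frame"))
}

#' @rdname env_table
#' @param path CSV path.
#' @export
read_env_table <- function(path, plots = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  env_table(df, plots)
}

#' Write a result table to CSV
#'
#' Round-trips losslessly through the matching `read_*` function: trait tables
#' serialise nominal code sets as ";"-joined cells, abundance matrices are
#' written wide with a `plot_id` column, any other data.frame is written
#' as plain CSV.
#'
#' @param table A `trait_table`, `abundance_matrix` or data.frame.
#' @param path Output path.
#' @export
write_table <- function(table, path) UseMethod("write_table")

#' @export
write_table.trait_table <- function(table, path) {
  schema <- attr(table, "schema")
  out <- as.data.frame(table)
  for (tn in names(schema)) {
    if (schema[[tn]]$kind == "nominal") {
      out[[tn]] <- vapply(table[[tn]], function(v) paste(v, collapse = ";"), "")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' @export
write_table.abundance_matrix <- function(table, path) {
  out <- data.frame(plot_id = rownames(table), as.data.frame(unclass(table)),
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
write_table.data.frame <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' Validate a traits / plots / environment triple
#'
#' Runs the three table validators plus cross-table identity checks, the same
#' checks the readers apply, on in-memory objects.
#'
#' @param traits A [trait_table()].
#' @param plots An [abundance_matrix()].
#' @param env An [env_table()].
#' @return `TRUE` invisibly; raises a classed error on the first failure.
#' @export
validate_dataset <- function(traits, plots, env) {
  trait_table(as.data.frame(traits), attr(traits, "schema"))
  abundance_matrix(unclass(plots), traits)
  env_table(as.data.frame(env), plots)
  invisible(TRUE)
}
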