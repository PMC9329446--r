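#' @include AllClasses.R utils.R
NULL

#' Read a variable schema from a YAML or JSON sidecar
#'
#' The schema maps every table column to a kind (\code{quantitative},
#' \code{ordinal}, \code{factor}, \code{binary}), an optional level set and an
#' optional non-negative Gower weight (default 1).  Example YAML:
#' \preformatted{
#' Hab:    {kind: factor, levels: [R, L, C]}
#' Impact: {kind: ordinal, levels: [0,1,2,3,4,5,6,7]}
#' Dis_dam: {kind: quantitative, weight: 1}
#' }
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return Named list of per-column entries \code{list(kind, levels, weight)}.
#' @export
readSchema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  out <- lapply(raw, function(e) {
    if (is.character(e) && length(e) == 1L) e <- list(kind = e)
    list(kind = e$kind,
         levels = if (is.null(e$levels)) NULL else unlist(e$levels),
         weight = if (is.null(e$weight)) 1 else as.numeric(e$weight))
  })
  bad <- vapply(out, function(e) !e$kind %in% .KINDS, TRUE)
  if (any(bad))
    stop("unknown kind for column(s): ", paste(names(out)[bad], collapse = ", "))
  w <- vapply(out, `[[`, numeric(1), "weight")
  if (any(w < 0)) stop("negative schema weight for column(s): ",
                       paste(names(out)[w < 0], collapse = ", "))
  out
}

#' Read a delimited table against a schema
#'
#' Reads a CSV or TSV file whose first column holds the row identifiers and
#' whose remaining columns are declared in \code{schema}.  Cells that are
#' empty or literal \code{NA} become missing values -- never silent zeros.
#' The file's columns and the schema must match exactly; any mismatch,
#' duplicated id, or value that cannot be coerced to its declared kind is a
#' hard error naming the offender.
#'
#' @param path path to a \code{.csv} or \code{.tsv}/\code{.txt} file.
#' @param schema a schema as returned by \code{\link{readSchema}}, or a
#'   named character vector of kinds.
#' @return A \linkS4class{SampleTable}.
#' @seealso \code{\link{writeSampleTable}}, \code{\link{alignRows}}
#' @export
readSampleTable <- function(path, schema) {
  if (!file.exists(path)) stop("table file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("", "NA"), comment.char = "",
                          quote = "\"")
  if (ncol(df) < 2L) stop("table needs an id column plus at least one variable")
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated row identifier(s): ", paste(dup, collapse = ", "))
  if (is.character(schema))
    schema <- lapply(schema, function(k) list(kind = k))
  schema <- lapply(schema, function(e) list(
    kind = e$kind,
    levels = if (is.null(e$levels)) NULL else unlist(e$levels),
    weight = if (is.null(e$weight)) 1 else as.numeric(e$weight)))
  cols <- colnames(df)[-1L]
  extra <- setdiff(cols, names(schema))
  if (length(extra))
    stop("column(s) present in file but absent from schema: ",
         paste(extra, collapse = ", "))
  absent <- setdiff(names(schema), cols)
  if (length(absent))
    stop("column(s) declared in schema but absent from file: ",
         paste(absent, collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  rownames(body) <- ids
  sampleTable(body,
              kinds = vapply(schema, `[[`, character(1), "kind")[cols],
              weights = vapply(schema, `[[`, numeric(1), "weight")[cols],
              levels = lapply(schema, `[[`, "levels")[cols])
}

#' Write a SampleTable to delimited text
#'
#' Inverse of \code{\link{readSampleTable}}: the id goes first under the
#' header \code{id}; missing values are written as empty cells.
#'
#' @param x a \linkS4class{SampleTable}.
#' @param path output path; \code{.tsv}/\code{.txt} selects tab separation.
#' @return \code{path}, invisibly.
#' @export
writeSampleTable <- function(x, path) {
  stopifnot(methods::is(x, "SampleTable"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  out <- cbind(id = rownames(x@data), x@data)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Schema of a SampleTable, writable as a sidecar
#'
#' @param x a \linkS4class{SampleTable}.
#' @param path optional output path (\code{.yaml} or \code{.json}); when
#'   given, the schema is written there.
#' @return The schema list, invisibly when written.
#' @export
tableSchema <- function(x, path = NULL) {
  stopifnot(methods::is(x, "SampleTable"))
  sch <- stats::setNames(lapply(colnames(x@data), function(cn) {
    e <- list(kind = unname(x@kinds[[cn]]))
    if (length(x@levels[[cn]])) e$levels <- x@levels[[cn]]
    if (x@weights[[cn]] != 1) e$weight <- unname(x@weights[[cn]])
    e
  }), colnames(x@data))
  if (!is.null(path)) {
    if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::write_json(sch, path, auto_unbox = TRUE, pretty = TRUE)
    else yaml::write_yaml(sch, path)
    return(invisible(sch))
  }
  sch
}

#' Align several tables on their common row identifiers
#'
#' All multi-matrix analyses require the site rows of every table to agree.
#' \code{alignRows} restricts each table to the identifiers common to all and
#' reorders them to the first table's order.  Identifiers dropped from each
#' table are reported in the \code{"dropped"} attribute of the result.
#'
#' @param tables a list of two or more \linkS4class{SampleTable}s.
#' @return The list of aligned tables (same length and names as the input)
#'   with attribute \code{dropped}: a list of the ids removed from each.
#' @examples
#' a <- sampleTable(data.frame(row.names = c("a", "b", "c"), v = 1:3))
#' b <- sampleTable(data.frame(row.names = c("c", "b", "d"), w = 4:6))
#' al <- alignRows(list(a, b))
#' sampleIDs(al[[2]])          # "b" "c"
#' attr(al, "dropped")
#' @export
alignRows <- function(tables) {
  if (length(tables) < 2L) stop("need at least two tables to align")
  stopifnot(all(vapply(tables, methods::is, TRUE, "SampleTable")))
  ids <- lapply(tables, function(t) rownames(t@data))
  common <- Reduce(intersect, ids)
  if (!length(common)) stop("no common row identifiers across tables")
  keep <- ids[[1L]][ids[[1L]] %in% common]
  out <- lapply(tables, function(t) {
    d <- t@data[keep, , drop = FALSE]
    methods::new("SampleTable", data = d, kinds = t@kinds,
                 weights = t@weights, levels = t@levels)
  })
  names(out) <- names(tables)
  attr(out, "dropped") <- lapply(ids, function(i) setdiff(i, keep))
  out
}

#' Species occurrence fixture: 28 freshwater mollusks over three periods
#'
#' The packaged occurrence record of the 28 freshwater mollusk species of a
#' dammed middle-river reach: species code, taxonomic class (gastropod or
#' bivalve), presence in each of three periods (T1, historical baseline; T2,
#' post-damming; T3, present day) and origin (native, NAT, or alien invasive,
#' AIS).  Shipped as plain CSV under \code{extdata/table1.csv}.
#'
#' @return A \code{data.frame} with columns \code{code}, \code{taxon_class},
#'   \code{T1}, \code{T2}, \code{T3}, \code{origin}; exactly 28 rows with
#'   unique codes and binary occurrences.
#' @examples
#' t1 <- loadTable1()
#' sum(t1$taxon_class == "gastropod" & t1$T3 == 1)   # 15
#' @export
loadTable1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "cuvarp",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(colnames(df),
                      c("code", "taxon_class", "T1", "T2", "T3", "origin")),
            nrow(df) == 28L, !anyDuplicated(df$code),
            all(unlist(df[c("T1", "T2", "T3")]) %in% c(0L, 1L)),
            all(df$taxon_class %in% c("gastropod", "bivalve")),
            all(df$origin %in% c("NAT", "AIS")))
  df
}

#' Marginal counts of the occurrence fixture
#'
#' @return Named integer vector of the fixture's marginals: total species,
#'   gastropods and bivalves overall, gastropods and bivalves present in T3,
#'   and alien invasive species.
#' @export
table1Counts <- function() {
  t1 <- loadTable1()
  c(species = nrow(t1),
    gastropods = sum(t1$taxon_class == "gastropod"),
    bivalves = sum(t1$taxon_class == "bivalve"),
    gastropods_T3 = sum(t1$taxon_class == "gastropod" & t1$T3 == 1),
    bivalves_T3 = sum(t1$taxon_class == "bivalve" & t1$T3 == 1),
    ais = sum(t1$origin == "AIS"))
}
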