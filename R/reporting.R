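#' @include AllClasses.R utils.R tables_io.R cuvarp_pipeline.R synthdata.R
NULL

#' Run the full cumulative-partitioning pipeline from files
#'
#' Executes read/validate/align, component construction, consensus axis
#' selection, reciprocal partitioning with tests, cumulative assembly and
#' diagram export, writing \code{result.json}, \code{diagram.json},
#' \code{diagram.svg}, \code{selection.log} and \code{run.log} (which echoes
#' every default and convention so the run is self-describing) into the
#' output directory.  Re-running with the same configuration and seed
#' produces byte-identical artifacts.  Any stage error is surfaced with the
#' stage name and the offending input.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \code{native}, \code{alien}, \code{env}, \code{coords} (CSV/TSV paths);
#'   \code{schema} (YAML/JSON sidecar whose top-level keys \code{native},
#'   \code{alien}, \code{env}, \code{coords} hold per-column schemas;
#'   omitted tables default to all-quantitative columns); \code{out}
#'   (output directory); \code{seed} (mandatory); and optionally
#'   \code{alpha} (default 0.05), \code{nPerm} (default 999),
#'   \code{design} (list \code{kind}, \code{blocks} = env column name,
#'   \code{mirror}, \code{shiftWithin}), \code{maxAxes},
#'   \code{floorNegatives} (default TRUE).
#' @return The \linkS4class{CuvarpResult}, invisibly.
#' @seealso \code{\link{validateResultJSON}}
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("[config] file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  for (f in c("native", "alien", "env", "coords", "out", "seed"))
    if (is.null(config[[f]])) stop("[config] missing required entry: ", f)
  alpha <- if (is.null(config$alpha)) 0.05 else as.numeric(config$alpha)
  if (alpha <= 0 || alpha >= 1) stop("[config] alpha must lie in (0,1)")
  nPerm <- if (is.null(config$nPerm)) 999L else as.integer(config$nPerm)
  seed <- as.integer(config$seed)

  schemas <- if (!is.null(config$schema))
    stopWithStage("schema", {
      if (!file.exists(config$schema))
        stop("schema file not found: ", config$schema)
      raw <- if (grepl("\\.json$", config$schema, ignore.case = TRUE))
        jsonlite::read_json(config$schema, simplifyVector = TRUE)
      else yaml::read_yaml(config$schema)
      lapply(raw, function(tab) lapply(tab, function(e) {
        if (is.character(e) && length(e) == 1L) e <- list(kind = e)
        list(kind = e$kind,
             levels = if (is.null(e$levels)) NULL else unlist(e$levels),
             weight = if (is.null(e$weight)) 1 else as.numeric(e$weight))
      }))
    })
  else list()

  readOne <- function(key) stopWithStage(paste0("read_", key), {
    path <- config[[key]]
    if (!file.exists(path)) stop("table file not found: ", path)
    sch <- schemas[[key]]
    if (is.null(sch)) {
      hdr <- utils::read.table(path, header = TRUE, nrows = 1,
                               sep = if (grepl("\\.(tsv|txt)$", path)) "\t" else ",",
                               check.names = FALSE)
      cols <- colnames(hdr)[-1L]
      sch <- stats::setNames(lapply(cols, function(.)
        list(kind = "quantitative", levels = NULL, weight = 1)), cols)
    }
    readSampleTable(path, sch)
  })
  tabs <- list(native = readOne("native"), alien = readOne("alien"),
               env = readOne("env"), coords = readOne("coords"))
  tabs <- stopWithStage("align_rows", alignRows(tabs))

  design <- stopWithStage("design", {
    ds <- config$design
    if (is.null(ds)) permutationDesign("free")
    else {
      blocks <- if (!is.null(ds$blocks)) {
        col <- ds$blocks
        if (!col %in% colnames(tabs$env@data))
          stop("blocks column '", col, "' not found in the environment table")
        as.character(tabs$env@data[[col]])
      }
      permutationDesign(ds$kind, blocks = blocks,
                        mirror = isTRUE(ds$mirror),
                        shiftWithin = isTRUE(ds$shiftWithin))
    }
  })

  comps <- stopWithStage("build_components",
    buildComponents(tabs$native, tabs$alien, tabs$env, tabs$coords))
  sel <- stopWithStage("select_axes",
    selectAxes(comps, alpha = alpha, nPerm = nPerm,
               seed = deriveSeed(seed, 1L), design = design,
               maxAxes = config$maxAxes))
  rv <- stopWithStage("reciprocal_varpart",
    reciprocalVarpart(sel, design = design, nPerm = nPerm,
                      seed = deriveSeed(seed, 2L)))
  res <- stopWithStage("assemble_cuvarp", assembleCuvarp(rv$varparts, rv$totals))

  outDir <- config$out
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stopWithStage("export", {
    exportDiagram(res,
                  floorNegatives = !isFALSE(config$floorNegatives),
                  jsonFile = file.path(outDir, "diagram.json"),
                  svgFile = file.path(outDir, "diagram.svg"))
    pct <- variationPercents(res@grandTotal, res@residualSum)
    payload <- list(
      parameters = list(alpha = alpha, n_perm = nPerm, seed = seed,
                        design = designSummary(design),
                        keep_policy = "positive",
                        dbmem_threshold = "auto (MST largest edge)",
                        variance_divisor = "n-1"),
      selected_axes = sel@axes,
      totals = as.list(res@totals),
      grand_total = res@grandTotal,
      explained = res@explainedSum, residual = res@residualSum,
      explained_percent = unname(pct[["explained"]]),
      residual_percent = unname(pct[["residual"]]),
      fractions = lapply(res@varparts, function(v)
        c(as.list(v@fractions), list(residual = v@residual))),
      tests = lapply(rv$tests, function(tl) lapply(tl, function(t)
        list(pseudo_F = t@statistic, p = t@pValue, n_perm = t@nPerm))),
      regions = res@regions[, c("subset", "value", "percent")])
    jsonlite::write_json(payload, file.path(outDir, "result.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(sel@selectionLog, file.path(outDir, "selection.log"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(c(
      "cuvarp run log",
      sprintf("alpha=%g nPerm=%d seed=%d", alpha, nPerm, seed),
      sprintf("design=%s", designSummary(design)),
      "keep_policy=positive (eigenvalues above 1e-8 relative tolerance)",
      "gower: ordinals as integer ranks, range-normalised; no Podani correction",
      "dbmem: auto threshold = MST largest edge; beyond-threshold set to 4t",
      "partial adjusted R2 by Peres-Neto subtraction of simple adjusted R2s",
      "FDR (Benjamini-Hochberg) within each forward-selection step",
      "totals computed on selected-axes tables, variance divisor n-1",
      sprintf("selected axes: %s",
              paste(sprintf("%s:{%s}", names(sel@axes),
                            vapply(sel@axes, paste, "", collapse = ",")),
                    collapse = " ")),
      if (length(sel@fallback))
        sprintf("WARNING: fallback to axis 1 for role(s): %s",
                paste(sel@fallback, collapse = ","))),
      file.path(outDir, "run.log"))
  })
  invisible(res)
}

#' Check the occurrence fixture against its published marginals
#'
#' Recomputes every marginal count of the packaged 28-species occurrence
#' table and compares it with the expected values (total species,
#' gastropods, bivalves, present-day gastropods and bivalves, alien
#' invasive species).
#'
#' @return A \code{data.frame} with columns \code{check}, \code{value},
#'   \code{expected}, \code{pass}.
#' @export
table1Checks <- function() {
  got <- table1Counts()
  expected <- c(species = 28L, gastropods = 17L, bivalves = 11L,
                gastropods_T3 = 15L, bivalves_T3 = 8L, ais = 6L)
  data.frame(check = names(expected),
             value = as.integer(got[names(expected)]),
             expected = as.integer(expected),
             pass = got[names(expected)] == expected,
             row.names = NULL)
}

#' Validate a pipeline result against the shipped JSON schema
#'
#' Structural validation of \code{result.json} against the schema published
#' with the package (\code{inst/schema/result-schema.json}): required keys,
#' object/array shapes and primitive types (the subset of JSON Schema the
#' shipped schema uses).
#'
#' @param x path to a result JSON file, or an already-parsed list.
#' @param schemaPath alternative schema path.
#' @return \code{TRUE} if valid, otherwise an error naming the first
#'   violation.
#' @export
validateResultJSON <- function(x,
                               schemaPath = system.file("schema",
                                                        "result-schema.json",
                                                        package = "cuvarp")) {
  obj <- if (is.character(x)) jsonlite::read_json(x) else x
  schema <- jsonlite::read_json(schemaPath)
  check <- function(o, s, at) {
    ty <- s$type
    ok <- switch(ty,
      object = is.list(o) && (is.null(names(o)) == (length(o) == 0L) ||
                                !is.null(names(o))),
      array = is.list(o) || is.vector(o),
      number = is.numeric(o) && length(o) == 1L,
      integer = is.numeric(o) && length(o) == 1L,
      string = is.character(o) && length(o) == 1L,
      boolean = is.logical(o) && length(o) == 1L,
      TRUE)
    if (!ok) stop(sprintf("schema violation at %s: expected %s", at, ty))
    if (ty == "object") {
      for (r in unlist(s$required))
        if (is.null(o[[r]]))
          stop(sprintf("schema violation at %s: missing required key '%s'",
                       at, r))
      for (pn in names(s$properties))
        if (!is.null(o[[pn]]))
          check(o[[pn]], s$properties[[pn]], paste0(at, ".", pn))
      if (!is.null(s$additionalProperties) &&
          is.list(s$additionalProperties))
        for (pn in setdiff(names(o), names(s$properties)))
          check(o[[pn]], s$additionalProperties, paste0(at, ".", pn))
    }
    if (ty == "array" && !is.null(s$items))
      for (i in seq_along(o)) check(o[[i]], s$items, sprintf("%s[%d]", at, i))
    invisible(TRUE)
  }
  check(obj, schema, "$")
  TRUE
}
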