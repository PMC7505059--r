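#' Reading and writing catalogue files
#'
#' Two dialects are supported. The `"appendix"` dialect is the
#' semicolon-separated one-line-per-species format used for printed
#' catalogue appendices:
#'
#' ```
#' family;genus;binomial;states;endemic;iucn;nom059;cites;banked;useful
#' ```
#'
#' where `states` is a comma-separated list of state codes (may be empty),
#' `endemic` is `endemic`/`non-endemic`, status fields use the printed
#' vocabularies (`P`/`A`/`Pr`, annex `I`/`II`/`II/NC`/`III`), the `banked`
#' field holds any of the tokens `banked` (in-country collection) and
#' `duplicated` (duplicated collection) separated by a comma, and `useful`
#' is the literal token `useful` or empty. Absent status fields parse as
#' NE / none: unassessed species simply omit them. The `"csv"` dialect is a
#' strict mirror with one column per attribute and logical flags.
#'
#' @name catalogue-io
#' @keywords internal
NULL

parse_appendix_line <- function(line) {
  f <- strsplit(line, ";", fixed = TRUE)[[1]]
  if (length(f) < 3 || length(f) > 10) {
    stop("expected 3-10 semicolon-separated fields, got ", length(f))
  }
  f <- c(trimws(f), rep("", 10 - length(f)))
  endemic_tok <- tolower(f[5])
  if (!endemic_tok %in% c("", "endemic", "non-endemic")) {
    stop("unknown endemic token: ", f[5])
  }
  banked_toks <- trimws(strsplit(f[9], ",", fixed = TRUE)[[1]])
  banked_toks <- banked_toks[nzchar(banked_toks)]
  bad <- setdiff(tolower(banked_toks), c("banked", "duplicated"))
  if (length(bad)) stop("unknown banked token: ", paste(bad, collapse = ", "))
  useful_tok <- tolower(f[10])
  if (!useful_tok %in% c("", "useful", "non-useful")) {
    stop("unknown useful token: ", f[10])
  }
  data.frame(
    family = f[1], genus = f[2], species = f[3], states = f[4],
    endemic = endemic_tok == "endemic",
    iucn = if (nzchar(f[6])) f[6] else "NE",
    nom059 = if (nzchar(f[7])) f[7] else "none",
    cites = if (nzchar(f[8])) f[8] else "none",
    banked_incountry = "banked" %in% tolower(banked_toks),
    banked_duplicated = "duplicated" %in% tolower(banked_toks),
    useful = useful_tok == "useful",
    stringsAsFactors = FALSE)
}

#' Load a species catalogue from a file
#'
#' Malformed lines are not silently dropped: they are collected into a
#' parse report (`$parse_report`, a data.frame of line numbers and
#' messages) while well-formed lines go through full [catalogue()]
#' validation, so duplicate binomials or unknown category codes raise an
#' error naming the offenders.
#'
#' @param path file to read.
#' @param dialect `"appendix"` (semicolon lines) or `"csv"`.
#' @param provenance metadata string stored on the catalogue; defaults to
#'   the path.
#' @return a [catalogue()], with a `parse_report` element (zero rows when
#'   every line parsed).
#' @export
load_catalogue <- function(path, dialect = c("appendix", "csv"),
                           provenance = path) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("catalogue file not found: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    for (col in c("endemic", "banked_incountry", "banked_duplicated", "useful")) {
      df[[col]] <- as.logical(df[[col]])
    }
    cat <- catalogue(df, provenance)
    cat$parse_report <- data.frame(line = integer(0), message = character(0))
    return(cat)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  rows <- vector("list", sum(keep))
  errs <- list()
  j <- 0L
  for (i in which(keep)) {
    parsed <- tryCatch(parse_appendix_line(lines[i]), error = identity)
    if (inherits(parsed, "error")) {
      errs[[length(errs) + 1L]] <-
        data.frame(line = i, message = conditionMessage(parsed))
    } else {
      j <- j + 1L
      rows[[j]] <- parsed
    }
  }
  if (j == 0L) stop("no parseable catalogue lines in ", path)
  cat <- catalogue(do.call(rbind, rows[seq_len(j)]), provenance)
  cat$parse_report <- if (length(errs)) do.call(rbind, errs) else
    data.frame(line = integer(0), message = character(0))
  cat
}

render_appendix_line <- function(e) {
  sprintf("%s;%s;%s;%s;%s;%s;%s;%s;%s;%s",
          e$family, e$genus, e$species, e$states,
          ifelse(e$endemic, "endemic", "non-endemic"),
          ifelse(e$iucn == "NE", "", e$iucn),
          ifelse(e$nom059 == "none", "", e$nom059),
          ifelse(e$cites == "none", "", e$cites),
          ifelse(e$banked_incountry & e$banked_duplicated, "banked,duplicated",
                 ifelse(e$banked_incountry, "banked",
                        ifelse(e$banked_duplicated, "duplicated", ""))),
          ifelse(e$useful, "useful", ""))
}

#' Write a catalogue in appendix or CSV form
#'
#' Species are written in alphabetical order of family, genus and species,
#' the printed catalogue convention; `load_catalogue()` on the result
#' reproduces the catalogue exactly (round trip).
#'
#' @param cat a validated [catalogue()].
#' @param path output file.
#' @inheritParams load_catalogue
#' @return invisibly, `path`.
#' @export
write_catalogue <- function(cat, path, dialect = c("appendix", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(cat, "catalogue"))
  e <- cat$entries
  e <- e[order(e$family, e$genus, e$species, method = "radix"), , drop = FALSE]
  if (dialect == "csv") {
    utils::write.csv(e, path, row.names = FALSE)
  } else {
    writeLines(render_appendix_line(e), path, useBytes = TRUE)
  }
  invisible(path)
}
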