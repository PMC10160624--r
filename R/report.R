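#' Confirmation results and report files
#'
#' Every confirmer returns an `lrc_result` with a three-way verdict:
#' `confirmed`, `not_confirmed`, or `insufficient_coverage` (local depth
#' below the applicable floor -- the variant is neither confirmed nor
#' refuted).  `evidence` is a kind-specific summary (pileup counts, repeat
#' profile, breakpoint support, ...); it is empty when coverage was
#' insufficient.
#'
#' @param query_id,kind identify the query
#' @param status one of "confirmed", "not_confirmed", "insufficient_coverage"
#' @param depth local depth (reads) at the decision point
#' @param evidence named list of quantitative evidence
#' @param notes free-text annotations
#' @return an object of class `lrc_result`
#' @export
confirmation_result <- function(query_id, kind, status, depth,
                                evidence = list(), notes = "") {
  status <- match.arg(status, c("confirmed", "not_confirmed", "insufficient_coverage"))
  if (status != "insufficient_coverage" && is.null(evidence))
    stop("evidence required unless coverage is insufficient")
  structure(list(query_id = as.character(query_id), kind = kind, status = status,
                 depth = as.numeric(depth), evidence = evidence,
                 notes = as.character(notes)),
            class = "lrc_result")
}

#' @export
print.lrc_result <- function(x, ...) {
  cat(sprintf("<result %s> [%s] %s (depth %s)\n", x$query_id, x$kind,
              x$status, format(x$depth)))
  if (nzchar(x$notes)) cat("  notes: ", x$notes, "\n", sep = "")
  if (length(x$evidence)) {
    ev <- x$evidence[vapply(x$evidence, function(e) is.atomic(e) && length(e) == 1, logical(1))]
    if (length(ev)) cat("  ", paste(names(ev), unlist(ev), sep = "=", collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

REPORT_SCHEMA <- "lrconfirm-report/1"

#' Write / read a confirmation report
#'
#' Reports round-trip losslessly: `read_report(write_report(x))` preserves
#' every field (evidence is serialized as JSON inside the TSV dialect).
#'
#' @param results list of [confirmation_result()] objects
#' @param path output file
#' @param format "tsv" or "json" (default: from file extension)
#' @return `path`, invisibly
#' @export
write_report <- function(results, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  stopifnot(all(vapply(results, inherits, logical(1), "lrc_result")))
  if (format == "json") {
    payload <- list(schema = REPORT_SCHEMA,
                    results = lapply(results, unclass))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste0("#schema=", REPORT_SCHEMA), con)
    df <- data.frame(
      query_id = vapply(results, `[[`, character(1), "query_id"),
      kind = vapply(results, `[[`, character(1), "kind"),
      status = vapply(results, `[[`, character(1), "status"),
      depth = vapply(results, `[[`, numeric(1), "depth"),
      notes = vapply(results, `[[`, character(1), "notes"),
      evidence_json = vapply(results, function(r)
        as.character(jsonlite::toJSON(r$evidence, auto_unbox = TRUE, digits = NA)),
        character(1)),
      stringsAsFactors = FALSE)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    payload <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!identical(payload$schema, REPORT_SCHEMA))
      stop("unrecognized report schema: ", payload$schema)
    lapply(payload$results, function(r)
      confirmation_result(r$query_id, r$kind, r$status, r$depth,
                          evidence = r$evidence, notes = r$notes))
  } else {
    first <- readLines(path, n = 1)
    if (!identical(first, paste0("#schema=", REPORT_SCHEMA)))
      stop("unrecognized report schema line: ", first)
    df <- read.delim(path, skip = 1, stringsAsFactors = FALSE,
                     colClasses = "character", quote = "")
    lapply(seq_len(nrow(df)), function(i)
      confirmation_result(df$query_id[i], df$kind[i], df$status[i],
                          as.numeric(df$depth[i]),
                          evidence = jsonlite::fromJSON(df$evidence_json[i],
                                                        simplifyVector = FALSE),
                          notes = df$notes[i]))
  }
}
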