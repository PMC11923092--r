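#' Read a delimited table with schema validation
#'
#' Reads a CSV or TSV file (delimiter auto-detected from the header line
#' unless given) and checks that the required columns are present and
#' numeric columns parse cleanly.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must be numeric; defaults to `required`.
#' @param sep Field separator; `NULL` auto-detects comma vs tab.
#' @return A data frame.
#' @export
read_table_auto <- function(path, required = character(),
                            numeric_cols = required, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  absent <- setdiff(required, names(df))
  if (length(absent) > 0) {
    stop("missing required column(s): ", paste(absent, collapse = ", "),
         " (found: ", paste(names(df), collapse = ", "), ")")
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) && !anyNA(df[[col]])) {
      stop("column '", col, "' contains non-numeric values")
    }
    df[[col]] <- v
  }
  df
}

#' Write a data frame as CSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read amino-acid sequences from a FASTA file
#'
#' Records are uppercased and validated against the 20-letter amino-acid
#' alphabet; an illegal residue is reported with its record and position.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta_aa <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- vapply(recs, function(r) toupper(as.character(r)[1]), character(1))
  for (nm in names(out)) {
    res <- strsplit(out[[nm]], "")[[1]]
    bad <- which(!res %in% names(kyte_doolittle))
    if (length(bad) > 0) {
      stop("record '", nm, "': illegal residue '", res[bad[1]],
           "' at position ", bad[1])
    }
  }
  out
}

#' Write an analysis report as JSON
#'
#' Serializes a results list to pretty-printed JSON with a provenance block
#' (schema version, package version, seed, input descriptions and timestamp
#' omitted for reproducibility unless requested).
#'
#' @param results Named list of results (numbers, vectors, data frames).
#' @param path Output path.
#' @param seed Seed used for the analysis, recorded in provenance.
#' @param inputs Character vector describing the inputs, recorded verbatim.
#' @return The path, invisibly.
#' @export
write_report <- function(results, path, seed = NA_integer_,
                         inputs = character()) {
  report <- list(
    schema_version = "1.0",
    provenance = list(
      package = "inteinkit",
      package_version = as.character(utils::packageVersion("inteinkit")),
      seed = seed,
      inputs = inputs
    ),
    results = results
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
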