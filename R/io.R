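# JSON record I/O. The schema (versioned, documented in
# inst/schema/record-schema.md) is:
#   { "schema_version": "1.0", "records": [ {record}, ... ] }
# or a bare array of records. Each record: smiles (string, required),
# scores (number array of per-atom or per-token length), attributes
# (ordered key/value object of strings), config (partial panel config),
# id (string). Unknown fields are preserved on round trip.

.SCHEMA_VERSION <- "1.0"
.RECORD_FIELDS <- c("smiles", "scores", "attributes", "config", "id")

.parseRecord <- function(x, index) {
  if (!is.list(x) || is.null(x$smiles) || !is.character(unlist(x$smiles)) ||
      length(unlist(x$smiles)) != 1L)
    stop("record ", index, ": missing or invalid 'smiles' field",
         call. = FALSE)
  smi <- as.character(unlist(x$smiles))
  id <- if (!is.null(x$id)) as.character(unlist(x$id)) else
    as.character(index)
  raw <- if (!is.null(x$scores)) as.numeric(unlist(x$scores)) else numeric(0)
  seq <- tokenizeSmiles(smi)
  if (length(raw) && !length(raw) %in% c(nAtoms(seq), nTokens(seq)))
    stop("record '", id, "': score vector of length ", length(raw),
         "; admissible lengths for '", smi, "' are ", nAtoms(seq),
         " (per atom) or ", nTokens(seq), " (per token)", call. = FALSE)
  if (length(raw) && any(!is.finite(raw)))
    stop("record '", id, "': scores must be finite numbers", call. = FALSE)
  attrs <- character(0)
  if (!is.null(x$attributes)) {
    attrs <- vapply(x$attributes, function(v) as.character(v)[1],
                    character(1))
  }
  cfg <- if (!is.null(x$config)) lapply(x$config, function(v)
    if (is.list(v)) v else unlist(v)) else list()
  extra <- x[setdiff(names(x), .RECORD_FIELDS)]
  new("SmilesRecord", smiles = smi, scores = raw, attributes = attrs,
      config = cfg, id = id, extra = extra)
}

#' Load molecule records from a JSON file
#'
#' Reads and validates a record file. Score vectors are checked against
#' both admissible lengths (atom count and token count of the record's
#' SMILES). By default invalid records are skipped with a logged warning
#' naming the record and the reason; in strict mode the first failure
#' aborts the load.
#'
#' @param path path to a JSON file (bare record array, or an object with
#'   \code{schema_version} and \code{records}).
#' @param strict abort on the first invalid record instead of skipping.
#' @return list of [SmilesRecord-class] objects.
#' @examples
#' path <- system.file("extdata", "example-records.json", package = "smivis")
#' recs <- loadRecords(path)
#' @export
loadRecords <- function(path, strict = FALSE) {
  if (!file.exists(path))
    stop("input file does not exist: '", path, "'", call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  recs <- if (is.list(doc) && !is.null(doc$records)) doc$records else doc
  if (!is.list(recs) || !length(recs))
    stop("'", path, "' contains no records", call. = FALSE)
  out <- list()
  for (i in seq_along(recs)) {
    r <- tryCatch(.parseRecord(recs[[i]], i), error = function(e) e)
    if (inherits(r, "error")) {
      if (strict) stop(conditionMessage(r), call. = FALSE)
      warning("skipping ", conditionMessage(r), call. = FALSE)
    } else {
      out[[length(out) + 1L]] <- r
    }
  }
  if (!length(out))
    stop("no valid records in '", path, "'", call. = FALSE)
  out
}

.recordToList <- function(rec) {
  out <- list(smiles = rec@smiles, id = rec@id)
  if (length(rec@scores)) out$scores <- rec@scores
  if (length(rec@attributes)) out$attributes <- as.list(rec@attributes)
  if (length(rec@config)) out$config <- rec@config
  c(out, rec@extra)
}

#' Save molecule records to a JSON file
#'
#' Writes records in the package's versioned schema. A file written by
#' \code{saveRecords} loads back identically with [loadRecords()]
#' (unknown fields included).
#'
#' @param records list of [SmilesRecord-class] objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
saveRecords <- function(records, path) {
  if (is(records, "SmilesRecord")) records <- list(records)
  stopifnot(is.list(records), length(records) > 0)
  doc <- list(schema_version = .SCHEMA_VERSION,
              records = lapply(records, .recordToList))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
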