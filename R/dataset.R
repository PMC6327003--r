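#' Assemble and validate an assay dataset
#'
#' An assay dataset holds the ordered mating events of one multiple-choice
#' assay: several replicate chambers run under one shared design. Events are
#' stored as a data frame with columns `replicate`, `order`, `female_class`
#' and `male_class`; any extra columns (e.g. wall-clock times or chamber
#' locations) are carried through untouched but never used by the model.
#'
#' Validation enforces the structural rules of an observed-to-exhaustion
#' assay: order ranks within a replicate form a contiguous 1..K sequence
#' (simultaneous copulations must be pre-broken by the recorder), class
#' labels belong to the design, at most `2 * n_females` events per replicate,
#' and — since realized female remating is excluded — no female class mates
#' more often than the design provides females.
#'
#' @param events data frame of mating events (see Details).
#' @param design an [assay_design()].
#' @param assay_id identifier recorded with the dataset.
#' @return An object of class `assay_dataset` with elements `design`,
#'   `events` and `assay_id`.
#' @examples
#' d <- assay_design(c("A", "B"), n_females = 2, n_males = 2)
#' ev <- data.frame(replicate = 1, order = 1:4,
#'                  female_class = c("A", "B", "A", "B"),
#'                  male_class = c("A", "B", "B", "A"))
#' assay_dataset(ev, d)
#' @export
assay_dataset <- function(events, design, assay_id = "assay1") {
  stopifnot(inherits(design, "assay_design"))
  events <- as.data.frame(events)
  required <- c("replicate", "order", "female_class", "male_class")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols))
    stop("events are missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  events$female_class <- as.character(events$female_class)
  events$male_class <- as.character(events$male_class)
  events$order <- as.integer(events$order)
  events$replicate <- as.character(events$replicate)
  if (nrow(events)) {
    events <- events[order(events$replicate, events$order), , drop = FALSE]
    rownames(events) <- NULL
  }
  x <- structure(list(design = design, events = events,
                      assay_id = as.character(assay_id)),
                 class = "assay_dataset")
  validate_assay(x)
  x
}

#' Validate an assay dataset against its design
#'
#' @param x an `assay_dataset`.
#' @return `x`, invisibly; otherwise an error describing the first violation.
#' @export
validate_assay <- function(x) {
  stopifnot(inherits(x, "assay_dataset"))
  ev <- x$events
  d <- x$design
  if (!nrow(ev)) return(invisible(x))
  bad <- !(ev$female_class %in% d$labels) | !(ev$male_class %in% d$labels)
  if (any(bad))
    stop(sprintf("unknown class label in row %d (labels must be %s)",
                 which(bad)[1], paste(d$labels, collapse = "/")),
         call. = FALSE)
  for (rep_id in unique(ev$replicate)) {
    ord <- ev$order[ev$replicate == rep_id]
    if (anyNA(ord) || !identical(sort(ord), seq_along(ord)))
      stop(sprintf("replicate %s: order ranks must be a contiguous 1..K sequence",
                   rep_id), call. = FALSE)
    if (length(ord) > 2L * d$n_females)
      stop(sprintf("replicate %s: %d events exceed the 2 x n_females bound (%d)",
                   rep_id, length(ord), 2L * d$n_females), call. = FALSE)
    fc <- ev$female_class[ev$replicate == rep_id]
    cnt <- table(factor(fc, levels = d$labels))
    if (any(cnt > d$n_females))
      stop(sprintf(
        "replicate %s: %d matings by class-%s females exceed the %d available (female remating is excluded)",
        rep_id, max(cnt), d$labels[which.max(cnt)], d$n_females),
        call. = FALSE)
  }
  invisible(x)
}

#' @export
print.assay_dataset <- function(x, ...) {
  cat(sprintf("Assay '%s': %d mating events in %d replicate(s)\n",
              x$assay_id, nrow(x$events), length(unique(x$events$replicate))))
  print(x$design)
  invisible(x)
}

#' Number of mating events in a dataset
#' @param x an `assay_dataset`.
#' @return integer event count.
#' @export
n_events <- function(x) {
  stopifnot(inherits(x, "assay_dataset"))
  nrow(x$events)
}

guess_sep <- function(path) {
  if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read ordered mating records from a delimited text file
#'
#' Expects a UTF-8 text table with a header row and columns `assay_id`,
#' `replicate`, `order`, `female_class`, `male_class` (extra columns are kept
#' as pass-through). Comma-separated by default; tab-separated files are
#' recognised by a `.tsv`/`.tab` extension or an explicit `sep`.
#'
#' @param path file path.
#' @param design the [assay_design()] the records must validate against.
#' @param assay if the file holds several assays, the `assay_id` to extract;
#'   a single-assay file needs no selection.
#' @param sep field separator; `NULL` (default) guesses from the extension.
#' @return A validated [assay_dataset()].
#' @seealso [write_assay()] for the inverse operation.
#' @export
read_assay <- function(path, design, assay = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sep %||% guess_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  required <- c("assay_id", "replicate", "order", "female_class", "male_class")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("input table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  ids <- unique(tab$assay_id)
  if (is.null(assay)) {
    if (length(ids) > 1L)
      stop("file holds assays ", paste(ids, collapse = ", "),
           "; pick one with `assay`", call. = FALSE)
    assay <- if (length(ids)) ids else "assay1"
  } else if (nrow(tab) && !assay %in% ids) {
    stop("assay_id '", assay, "' not present in file", call. = FALSE)
  }
  tab <- tab[tab$assay_id == assay | !nrow(tab), , drop = FALSE]
  tab$assay_id <- NULL
  assay_dataset(tab, design, assay_id = assay)
}

#' Write an assay dataset to a delimited text file
#'
#' Writes the canonical columns (`assay_id`, `replicate`, `order`,
#' `female_class`, `male_class`) plus any pass-through columns, so that
#' [read_assay()] recovers the dataset exactly.
#'
#' @param dataset an [assay_dataset()].
#' @param path output path.
#' @param sep field separator; `NULL` guesses from the extension.
#' @return `dataset`, invisibly.
#' @export
write_assay <- function(dataset, path, sep = NULL) {
  validate_assay(dataset)
  sep <- sep %||% guess_sep(path)
  ev <- dataset$events
  out <- cbind(assay_id = rep(dataset$assay_id, nrow(ev)), ev)
  if (!nrow(ev))
    out <- data.frame(assay_id = character(), replicate = character(),
                      order = integer(), female_class = character(),
                      male_class = character())
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(dataset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
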