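#' Construct a graded response model item
#'
#' A graded item is defined by one discrimination (slope) parameter `a` on the
#' logistic metric and `m - 1` strictly increasing threshold parameters `b` for
#' an item with `m` ordered response categories, coded `1..m`.
#'
#' @param id Short unique item identifier.
#' @param a Positive slope (discrimination) parameter.
#' @param b Numeric vector of strictly increasing thresholds.
#' @param label Optional free-text item description.
#' @return An object of class `graded_item`.
#' @examples
#' graded_item("it1", a = 2, b = c(-1, 0, 1.5))
#' @export
graded_item <- function(id, a, b, label = "") {
  item <- structure(
    list(id = as.character(id), label = as.character(label),
         a = as.numeric(a), b = as.numeric(b)),
    class = "graded_item")
  bad <- validate_graded_item(item)
  if (length(bad)) stop("invalid item '", id, "': ", paste(bad, collapse = "; "),
                        call. = FALSE)
  item
}

validate_graded_item <- function(item) {
  out <- character()
  if (length(item$a) != 1L || is.na(item$a) || item$a <= 0)
    out <- c(out, "slope must be a single positive number")
  if (length(item$b) < 1L || anyNA(item$b))
    out <- c(out, "at least one finite threshold required")
  else if (any(diff(item$b) <= 0))
    out <- c(out, "thresholds not ascending")
  out
}

#' @export
print.graded_item <- function(x, ...) {
  cat(sprintf("<graded_item> %s (%d categories)\n", x$id, length(x$b) + 1L))
  if (nzchar(x$label)) cat("  ", x$label, "\n", sep = "")
  cat(sprintf("  a = %.3f, b = (%s)\n", x$a,
              paste(formatC(x$b, format = "f", digits = 3), collapse = ", ")))
  invisible(x)
}

#' Construct an item bank
#'
#' An item bank is an ordered collection of [graded_item()]s sharing one latent
#' trait. The bank carries its orientation (for the bundled AAQ bank, higher
#' theta means more activity limitation) and implies the raw sum-score range
#' `S_min = n items` (all lowest categories) to `S_max = sum of category
#' counts` (all highest).
#'
#' @param items List of `graded_item` objects.
#' @param name Optional bank name.
#' @param orientation Orientation tag; the default records that larger latent
#'   values mean more limitation.
#' @param validate Raise an error on invariant violations (default). With
#'   `FALSE` the bank is built as-is so that [validate_item_bank()] can report.
#' @return An object of class `item_bank`.
#' @seealso [aaq_bank()], [read_item_bank()], [validate_item_bank()]
#' @export
item_bank <- function(items, name = "", orientation = "higher_theta_more_limitation",
                      validate = TRUE) {
  bank <- structure(list(items = items, name = name, orientation = orientation),
                    class = "item_bank")
  if (validate) {
    bad <- validate_item_bank(bank)
    if (length(bad)) stop("invalid item bank: ", paste(bad, collapse = "; "),
                          call. = FALSE)
  }
  bank
}

#' Validate an item bank
#'
#' Checks every item invariant (positive slope, strictly ascending thresholds)
#' plus bank-level invariants (non-empty, unique ids). Unlike the constructors
#' this never raises; it reports.
#'
#' @param bank An `item_bank`.
#' @return Character vector of violation descriptions, each naming the item and
#'   rule; empty when the bank is valid.
#' @export
validate_item_bank <- function(bank) {
  out <- character()
  if (length(bank$items) == 0L) return("bank has no items")
  ids <- vapply(bank$items, function(it) it$id, "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) out <- c(out, paste0("duplicate id '", dup, "'"))
  for (it in bank$items) {
    bad <- validate_graded_item(it)
    if (length(bad)) out <- c(out, paste0("item '", it$id, "': ", bad))
    if (isTRUE(attr(it$b, "needs_recalibration")))
      out <- c(out, paste0("item '", it$id, "': requires recalibration"))
  }
  out
}

#' @export
length.item_bank <- function(x) length(x$items)

#' Number of response categories per item
#' @param bank An `item_bank`.
#' @return Integer vector, one entry per item.
#' @export
n_categories <- function(bank) {
  vapply(bank$items, function(it) length(it$b) + 1L, 0L)
}

item_ids <- function(bank) vapply(bank$items, function(it) it$id, "")

#' Raw sum-score range of a bank
#'
#' With categories coded `1..m_i`, the raw sum score over complete patterns
#' ranges from `S_min` (number of items) to `S_max` (sum of category counts).
#'
#' @param bank An `item_bank`.
#' @return Named numeric vector `c(s_min=, s_max=)`.
#' @export
sum_score_range <- function(bank) {
  m <- n_categories(bank)
  c(s_min = length(m), s_max = sum(m))
}

#' The bundled AAQ item bank
#'
#' The published graded-response-model parameters of the 17-item Animated
#' Activity Questionnaire: one slope and 2-5 thresholds per item, calibrated on
#' an international hip/knee osteoarthritis sample with the latent trait
#' anchored to mean 0, SD 1, higher values meaning more activity limitation.
#'
#' @return An `item_bank` with 17 items (sum-score range 17-85).
#' @examples
#' bank <- aaq_bank()
#' summary(bank)
#' @export
aaq_bank <- function() {
  read_item_bank(system.file("extdata", "aaq_bank.json", package = "aaqcat",
                             mustWork = TRUE))
}

#' Read an item bank from JSON or CSV
#'
#' JSON is the canonical format: `{"items": [{"id", "label", "a", "b": [...]},
#' ...], "orientation": ...}`. CSV holds one row per item with columns
#' `id,label,a,b1,b2,...`; unused threshold cells are left blank, which encodes
#' banks with varying category counts.
#'
#' @param path File path; format chosen by extension (`.json` or `.csv`).
#' @return An `item_bank`. Malformed rows (non-positive slope, non-ascending
#'   thresholds, duplicate ids) raise an error naming the item.
#' @export
read_item_bank <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    raw <- jsonlite::read_json(path)
    items <- lapply(raw$items, function(r) {
      graded_item(r$id, a = r$a, b = unlist(r$b),
                  label = if (is.null(r$label)) "" else r$label)
    })
    item_bank(items, name = if (is.null(raw$name)) "" else raw$name,
              orientation = if (is.null(raw$orientation))
                "higher_theta_more_limitation" else raw$orientation)
  } else if (ext == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    bcols <- grep("^b[0-9]+$", names(tab), value = TRUE)
    bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
    items <- lapply(seq_len(nrow(tab)), function(r) {
      b <- as.numeric(tab[r, bcols])
      graded_item(tab$id[r], a = tab$a[r], b = b[!is.na(b)],
                  label = if ("label" %in% names(tab)) tab$label[r] else "")
    })
    item_bank(items)
  } else stop("unsupported bank format: .", ext, call. = FALSE)
}

#' Write an item bank to JSON or CSV
#'
#' Round-trips all numeric fields at full stored precision.
#'
#' @param bank An `item_bank`.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- list(
      name = bank$name, orientation = bank$orientation,
      items = lapply(bank$items, function(it)
        list(id = it$id, label = it$label, a = it$a, b = as.numeric(it$b))))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (ext == "csv") {
    m <- n_categories(bank)
    nb <- max(m) - 1L
    rows <- t(vapply(bank$items, function(it)
      c(it$b, rep(NA_real_, nb - length(it$b))), numeric(nb)))
    colnames(rows) <- paste0("b", seq_len(nb))
    tab <- data.frame(id = item_ids(bank),
                      label = vapply(bank$items, function(it) it$label, ""),
                      a = vapply(bank$items, function(it) it$a, 0),
                      rows, check.names = FALSE)
    utils::write.csv(tab, path, row.names = FALSE, na = "")
  } else stop("unsupported bank format: .", ext, call. = FALSE)
  invisible(path)
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank>%s %d items, categories %s\n",
              if (nzchar(x$name)) paste0(" ", x$name, ":") else "",
              length(x), paste(range(n_categories(x)), collapse = "-")))
  cat("  orientation:", x$orientation, "\n")
  invisible(x)
}

#' Summarise an item bank
#'
#' @param object An `item_bank`.
#' @param ... Unused.
#' @return A `summary.item_bank` list: item count, slope and threshold extrema,
#'   category counts and the raw sum-score range.
#' @export
summary.item_bank <- function(object, ...) {
  if (length(object) == 0L) stop("empty bank", call. = FALSE)
  a <- vapply(object$items, function(it) it$a, 0)
  ball <- unlist(lapply(object$items, function(it) it$b))
  rng <- sum_score_range(object)
  structure(list(
    n_items = length(object),
    slope_range = range(a),
    threshold_range = range(ball),
    n_thresholds = length(ball),
    categories = n_categories(object),
    s_min = unname(rng["s_min"]), s_max = unname(rng["s_max"])),
    class = "summary.item_bank")
}

#' @export
print.summary.item_bank <- function(x, ...) {
  cat(sprintf("Item bank: %d items, %d thresholds\n", x$n_items, x$n_thresholds))
  cat(sprintf("  slopes      %.3f - %.3f\n", x$slope_range[1], x$slope_range[2]))
  cat(sprintf("  thresholds  %.3f - %.3f\n", x$threshold_range[1], x$threshold_range[2]))
  cat(sprintf("  categories  %s\n", paste(x$categories, collapse = " ")))
  cat(sprintf("  sum-score range %d - %d\n", x$s_min, x$s_max))
  invisible(x)
}

#' Collapse response categories of one item
#'
#' Merges adjacent response categories of a single item and recodes the
#' response matrix accordingly, as done when disordered thresholds are found.
#' The returned bank entry for the item is a shell with `m' - 1` empty
#' threshold slots flagged as requiring recalibration: collapsing does not
#' invent new thresholds, the caller refits (see [grm()]).
#'
#' @param bank An `item_bank`.
#' @param responses Integer response matrix (respondents x items, categories
#'   `1..m_i`).
#' @param item Item id or index to collapse.
#' @param map Integer vector of length `m` mapping each old category `1..m`
#'   onto new categories; must be onto a contiguous `1..m'` range and
#'   order-preserving (e.g. `c(1, 2, 3, 4, 4)` merges the top two of five).
#' @return List with elements `bank` (shell entry for `item`) and `responses`
#'   (recoded matrix).
#' @export
collapse_categories <- function(bank, responses, item, map) {
  idx <- if (is.character(item)) match(item, item_ids(bank)) else as.integer(item)
  if (is.na(idx) || idx < 1L || idx > length(bank))
    stop("unknown item: ", item, call. = FALSE)
  m <- n_categories(bank)[idx]
  map <- as.integer(map)
  if (length(map) != m) stop("merge map must have one entry per category", call. = FALSE)
  if (any(diff(map) < 0L) || any(diff(map) > 1L) || map[1] != 1L)
    stop("merge map must be order-preserving onto a contiguous 1..m' range",
         call. = FALSE)
  m2 <- map[m]
  responses[, idx] <- map[responses[, idx]]
  it <- bank$items[[idx]]
  if (m2 < m) {
    b <- rep(NA_real_, m2 - 1L)
    attr(b, "needs_recalibration") <- TRUE
    it$b <- b
    bank$items[[idx]] <- it
  }
  list(bank = bank, responses = responses)
}
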