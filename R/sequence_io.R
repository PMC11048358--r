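#' Construct a validated set of fixed-length RNA windows
#'
#' A windows table is the package's central data structure: one row per
#' candidate site, holding a fixed-length RNA fragment (the *window*,
#' length `lambda`) centered on a uridine, plus an optional binary label
#' (1 = pseudouridine site, 0 = non-site). Benchmarks in this field use
#' `lambda = 21` (human/mouse) or `lambda = 31` (yeast).
#'
#' Sequences are normalized before validation: lowercase is uppercased and
#' DNA-style `T` is silently converted to `U` (public PseU datasets mix the
#' two alphabets). After normalization every character must be one of
#' `A`, `C`, `G`, `U`, all sequences must share one odd length, and labels
#' must be all present or all absent.
#'
#' @param x A data frame with columns `id` (character), `sequence`
#'   (character) and optionally `label` (0/1 or `NA`).
#' @param center_u How to treat windows whose center base (position
#'   `(lambda+1)/2`, 1-based) is not `U`: `"require"` errors (training
#'   default), `"warn"` keeps them with a warning (prediction input),
#'   `"off"` skips the check.
#' @return A tibble of class `pseu_windows` with columns `id`, `sequence`,
#'   `label` and attribute `window_length`.
#' @examples
#' rna_windows(tibble::tibble(
#'   id = c("a", "b"),
#'   sequence = c("ACGUUUGCA", "GGGAUAGGG"),
#'   label = c(1, 0)
#' ))
#' @export
rna_windows <- function(x, center_u = c("require", "warn", "off")) {
  center_u <- match.arg(center_u)
  stopifnot(is.data.frame(x))
  if (!all(c("id", "sequence") %in% names(x))) {
    abort_data("`x` must have columns `id` and `sequence`.")
  }
  out <- tibble(
    id = as.character(x$id),
    sequence = normalize_rna(as.character(x$sequence)),
    label = if ("label" %in% names(x)) as.integer(x$label) else NA_integer_
  )

  if (nrow(out) > 0) {
    bad_chr <- grepl("[^ACGU]", out$sequence)
    if (any(bad_chr)) {
      abort_data(paste0(
        "Non-ACGU characters after normalization in record(s): ",
        toString(out$id[bad_chr])
      ))
    }
    lens <- nchar(out$sequence)
    lambda <- lens[1]
    if (any(lens != lambda)) {
      abort_data(paste0(
        "Inconsistent window lengths (expected ", lambda, "): ",
        toString(sprintf("%s (%d)", out$id[lens != lambda], lens[lens != lambda]))
      ))
    }
    if (lambda %% 2 == 0) {
      abort_data(paste0("Window length must be odd (center base); got ", lambda, "."))
    }
    if (center_u != "off") {
      ctr <- substr(out$sequence, (lambda + 1) / 2, (lambda + 1) / 2)
      off_center <- ctr != "U"
      if (any(off_center)) {
        msg <- paste0(
          "Center base is not U in record(s): ", toString(out$id[off_center])
        )
        if (center_u == "require") abort_data(msg) else warn(msg)
      }
    }
    has_lab <- !is.na(out$label)
    if (any(has_lab) && !all(has_lab)) {
      abort_data(paste0(
        "Labels must be all present or all absent; missing for: ",
        toString(out$id[!has_lab])
      ))
    }
    if (any(has_lab) && !all(out$label[has_lab] %in% c(0L, 1L))) {
      abort_data("Labels must be binary (0 = non-site, 1 = PseU site).")
    }
  } else {
    lambda <- NA_integer_
  }

  structure(out,
    window_length = as.integer(lambda),
    class = c("pseu_windows", class(out))
  )
}

normalize_rna <- function(seqs) {
  chartr("T", "U", toupper(seqs))
}

#' Window length of a windows table
#'
#' @param x A `pseu_windows` tibble (or any data frame with a `sequence`
#'   column, in which case the common sequence length is returned).
#' @return Integer window length `lambda` (`NA` for an empty table).
#' @export
window_length <- function(x) {
  wl <- attr(x, "window_length")
  if (!is.null(wl)) return(wl)
  if (nrow(x) == 0) return(NA_integer_)
  unique(nchar(x$sequence))[1]
}

window_labels <- function(x) {
  if (!"label" %in% names(x) || all(is.na(x$label))) return(NULL)
  as.integer(x$label)
}

#' Read labeled RNA windows from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a validated windows
#' table. Three labeling conventions are supported: `"header"` reads a
#' trailing `|0` / `|1` token from each FASTA header (and strips it from
#' the id); `"table"` joins labels from a two-column tab-separated file
#' (`id<TAB>label`); `"none"` yields an unlabeled table.
#'
#' @param path Path to a FASTA file.
#' @param labels Labeling convention, see above. With `"header"`, files
#'   whose headers carry no `|0`/`|1` token load as unlabeled.
#' @param label_file Path to the TSV label table when `labels = "table"`.
#' @param center_u Passed to [rna_windows()]; use `"warn"` for prediction
#'   input.
#' @param dedupe Drop exact duplicate sequences (first occurrence kept)?
#'   Off by default.
#' @return A `pseu_windows` tibble.
#' @seealso [write_rna_windows()] for the inverse operation.
#' @export
read_rna_windows <- function(path, labels = c("header", "table", "none"),
                             label_file = NULL,
                             center_u = c("require", "warn", "off"),
                             dedupe = FALSE) {
  labels <- match.arg(labels)
  center_u <- match.arg(center_u)
  if (!file.exists(path)) abort_data(paste0("No such file: ", path))
  if (file.size(path) == 0) {
    return(rna_windows(tibble(id = character(), sequence = character())))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort_data(paste0("Malformed FASTA in ", path, ": ", conditionMessage(e)))
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  lab <- NA_integer_
  if (labels == "header") {
    has_tok <- grepl("\\|[01]$", ids)
    if (all(has_tok) && length(ids) > 0) {
      lab <- as.integer(sub("^.*\\|", "", ids))
      ids <- sub("\\|[01]$", "", ids)
    } else if (any(has_tok)) {
      abort_data(paste0(
        "Header label token |0/|1 present on some records but not all; ",
        "missing for: ", toString(ids[!has_tok])
      ))
    }
  } else if (labels == "table") {
    if (is.null(label_file)) abort_data("`label_file` is required when labels = \"table\".")
    tab <- read.table(label_file, sep = "\t", header = FALSE,
                      col.names = c("id", "label"),
                      colClasses = c("character", "integer"))
    m <- match(ids, tab$id)
    if (anyNA(m)) {
      abort_data(paste0("No label for record(s): ", toString(ids[is.na(m)])))
    }
    lab <- tab$label[m]
  }
  out <- tibble(id = ids, sequence = seqs, label = lab)
  if (dedupe) out <- out[!duplicated(normalize_rna(out$sequence)), ]
  rna_windows(out, center_u = center_u)
}

#' Write RNA windows to a FASTA file
#'
#' Labels, when present, are appended to headers as a trailing `|0`/`|1`
#' token, so that [read_rna_windows()] round-trips ids, sequences and
#' labels exactly.
#'
#' @param x A windows table (see [rna_windows()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rna_windows <- function(x, path) {
  x <- as_tibble(x)
  hdr <- x$id
  if ("label" %in% names(x) && nrow(x) > 0 && !all(is.na(x$label))) {
    hdr <- paste0(hdr, "|", x$label)
  }
  set <- Biostrings::BStringSet(setNames(x$sequence, hdr))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' @export
print.pseu_windows <- function(x, ...) {
  lab <- window_labels(x)
  cat(sprintf(
    "<pseu_windows> %d window(s), lambda = %s, %s\n",
    nrow(x), window_length(x),
    if (is.null(lab)) "unlabeled"
    else sprintf("%d positive / %d negative", sum(lab == 1), sum(lab == 0))
  ))
  NextMethod()
}

# internal: validated labeled windows or error naming the stage
require_labeled <- function(x, stage) {
  y <- window_labels(x)
  if (is.null(y)) abort_data(paste0(stage, ": windows must be labeled."))
  if (length(unique(y)) < 2) {
    abort_data(paste0(stage, ": both classes must be present."))
  }
  y
}

# validation failures are classed so the CLI can map them to a distinct
# exit code
abort_data <- function(msg) abort(msg, class = "data_error")
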