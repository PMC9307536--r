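#' Construct a label vocabulary
#'
#' A vocabulary is the ordered set of class names for one labelling task
#' (e.g. the 3 surgical phases or 7 surgical steps of a pituitary
#' operation). Class index `i` always refers to `vocabulary[i]`, so the
#' order of the vector is part of the contract: it fixes which classes are
#' "neighbours" for the simulator and the column order of every confusion
#' matrix.
#'
#' @param labels Character vector of unique class names. Names are
#'   restricted to `[A-Za-z0-9_-]` so sequence CSV files never need quoting.
#' @param task Short description of the task (e.g. `"phases"`, `"steps"`).
#' @return A character vector of class names with attribute `task`.
#' @examples
#' label_vocabulary(c("P1", "P2", "P3"), task = "phases")
#' @export
label_vocabulary <- function(labels, task = "labels") {
  labels <- as.character(labels)
  if (length(labels) == 0L) {
    rlang::abort("vocabulary error: `labels` must be nonempty")
  }
  if (anyDuplicated(labels)) {
    rlang::abort(paste0(
      "vocabulary error: duplicated label '",
      labels[duplicated(labels)][1L], "'"
    ))
  }
  bad <- grep("^[A-Za-z0-9_-]+$", labels, invert = TRUE, value = TRUE)
  if (length(bad) > 0L) {
    rlang::abort(paste0(
      "vocabulary error: label '", bad[1L],
      "' contains characters outside [A-Za-z0-9_-]"
    ))
  }
  structure(labels, task = task)
}

#' Read / write a vocabulary as JSON
#'
#' The on-disk form is a JSON array of class names in index order, e.g.
#' `["P1","P2","P3"]`. Keeping the vocabulary in its own file makes the
#' index order explicit rather than inferred from whichever labels happen
#' to occur in a sequence file.
#'
#' @param path File path of the JSON vocabulary.
#' @param vocabulary Character vector of class names (see
#'   [label_vocabulary()]).
#' @param task Task name attached to the vocabulary on read.
#' @return `read_vocabulary()` returns the vocabulary; `write_vocabulary()`
#'   returns `path` invisibly.
#' @export
read_vocabulary <- function(path, task = "labels") {
  if (!file.exists(path)) {
    rlang::abort(paste0("I/O error: vocabulary file not found: ", path))
  }
  label_vocabulary(jsonlite::fromJSON(path), task = task)
}

#' @rdname read_vocabulary
#' @export
write_vocabulary <- function(vocabulary, path) {
  jsonlite::write_json(as.character(vocabulary), path)
  invisible(path)
}

#' Construct a frame-wise label sequence
#'
#' A label sequence is one video's labels sampled at 1 Hz: one row per
#' second, frames numbered contiguously from 0. It is stored as a tibble
#' with columns `video_id`, `frame` and `label`, where `label` is a factor
#' whose levels are the vocabulary in index order. Both ground-truth
#' annotations and classifier predictions use this representation.
#'
#' @param labels Character vector or factor of per-frame class names, one
#'   per second, or an integer vector of 1-based class indices.
#' @param vocabulary Character vector of class names in index order.
#' @param video_id Identifier of the source video.
#' @return A tibble with columns `video_id` (character), `frame`
#'   (0-based integer) and `label` (factor over `vocabulary`).
#' @examples
#' vocab <- label_vocabulary(c("P1", "P2", "P3"))
#' label_sequence(c("P1", "P1", "P2"), vocab)
#' @export
label_sequence <- function(labels, vocabulary, video_id = "video") {
  vocabulary <- as.character(vocabulary)
  if (is.numeric(labels)) {
    idx <- as.integer(labels)
    if (length(idx) > 0L && (anyNA(idx) || any(idx < 1L) || any(idx > length(vocabulary)))) {
      rlang::abort("vocabulary error: class index outside [1, K]")
    }
    labels <- vocabulary[idx]
  }
  labels <- as.character(labels)
  if (length(labels) == 0L) {
    rlang::abort("sequence error: a label sequence must contain at least one frame")
  }
  f <- factor(labels, levels = vocabulary)
  if (anyNA(f)) {
    unknown <- setdiff(unique(labels), vocabulary)[1L]
    rlang::abort(paste0("vocabulary error: unknown label '", unknown, "'"))
  }
  tibble::tibble(
    video_id = as.character(video_id),
    frame = seq_along(labels) - 1L,
    label = f
  )
}

# Internal: checks the sequence tibble contract and returns it unchanged.
validate_sequence <- function(seq, arg = "seq") {
  if (!is.data.frame(seq) || !all(c("frame", "label") %in% names(seq))) {
    rlang::abort(paste0("`", arg, "` must be a label-sequence tibble with columns frame, label"))
  }
  if (nrow(seq) == 0L) {
    rlang::abort(paste0("sequence error: `", arg, "` has no frames"))
  }
  if (!is.factor(seq$label) || anyNA(seq$label)) {
    rlang::abort(paste0("sequence error: `", arg, "`$label must be an NA-free factor"))
  }
  if (!identical(as.integer(seq$frame), seq_len(nrow(seq)) - 1L)) {
    rlang::abort(paste0("sequence error: `", arg, "`$frame must be contiguous from 0"))
  }
  invisible(seq)
}

# Internal: 1-based integer codes of a sequence tibble / factor / character.
seq_codes <- function(x) {
  if (is.data.frame(x)) {
    return(as.integer(x$label))
  }
  if (is.factor(x)) {
    return(as.integer(x))
  }
  as.integer(x)
}

# Internal: vocabulary (factor levels) of a sequence tibble or factor.
seq_vocab <- function(x) {
  if (is.data.frame(x)) levels(x$label) else levels(x)
}

# Internal: same sequence with frames relabelled from integer codes.
seq_with_codes <- function(seq, codes) {
  seq$label <- factor(seq_vocab(seq)[codes], levels = seq_vocab(seq))
  seq
}

#' Read a frame-wise label sequence from CSV
#'
#' The interchange format is a two-column CSV with header `frame,label`:
#' `frame` must run 0, 1, 2, ... without gaps or duplicates (1 Hz sampling,
#' no missing seconds) and every `label` must belong to the supplied
#' vocabulary. Labels are stored as names, not indices, so files are
#' self-describing.
#'
#' @param path Path of the CSV file.
#' @param vocabulary Character vector of class names in index order.
#' @param video_id Video identifier; defaults to the file name without
#'   extension.
#' @return A label-sequence tibble (see [label_sequence()]).
#' @export
read_sequence <- function(path, vocabulary, video_id = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("I/O error: file not found: ", path))
  }
  if (is.null(video_id)) {
    video_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!identical(names(df), c("frame", "label"))) {
    rlang::abort(paste0(
      "format error: expected header 'frame,label', got '",
      paste(names(df), collapse = ","), "'"
    ))
  }
  if (nrow(df) == 0L) {
    rlang::abort("format error: sequence file contains no frames")
  }
  df$frame <- suppressWarnings(as.integer(df$frame))
  expected <- seq_len(nrow(df)) - 1L
  off <- which(is.na(df$frame) | df$frame != expected)
  if (length(off) > 0L) {
    rlang::abort(paste0(
      "format error: non-contiguous frame index at row ", off[1L],
      " (found ", df$frame[off[1L]], ", expected ", expected[off[1L]], ")"
    ))
  }
  label_sequence(df$label, vocabulary, video_id = video_id)
}

#' Write a frame-wise label sequence to CSV
#'
#' Writes the `frame,label` CSV described in [read_sequence()]: UTF-8,
#' LF line endings, labels serialised as class names. Reading the file
#' back with the same vocabulary reproduces the sequence exactly.
#'
#' @param seq A label-sequence tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  validate_sequence(seq)
  df <- tibble::tibble(frame = as.integer(seq$frame), label = as.character(seq$label))
  tryCatch(
    readr::write_csv(df, path, eol = "\n"),
    error = function(e) {
      rlang::abort(paste0("I/O error: cannot write '", path, "': ", conditionMessage(e)))
    }
  )
  invisible(path)
}

#' Pair a prediction with its ground truth
#'
#' Evaluation and supervised HMM fitting always work on aligned
#' (ground truth, prediction) pairs from the same video: equal length,
#' same vocabulary, same video. The pair is a tibble with one row per
#' frame and factor columns `truth` and `pred`.
#'
#' @param truth Ground-truth label-sequence tibble.
#' @param pred Predicted label-sequence tibble.
#' @return A tibble with columns `video_id`, `frame`, `truth`, `pred`.
#' @examples
#' vocab <- label_vocabulary(c("A", "B"))
#' gt <- label_sequence(c("A", "A", "B"), vocab)
#' pr <- label_sequence(c("A", "B", "B"), vocab)
#' make_pair(gt, pr)
#' @export
make_pair <- function(truth, pred) {
  validate_sequence(truth, "truth")
  validate_sequence(pred, "pred")
  if (nrow(truth) != nrow(pred)) {
    rlang::abort(paste0(
      "pairing error: ground truth has ", nrow(truth),
      " frames but prediction has ", nrow(pred), " frames"
    ))
  }
  if (!identical(seq_vocab(truth), seq_vocab(pred))) {
    rlang::abort(paste0(
      "pairing error: vocabulary mismatch ([",
      paste(seq_vocab(truth), collapse = ","), "] vs [",
      paste(seq_vocab(pred), collapse = ","), "])"
    ))
  }
  tv <- unique(as.character(truth$video_id))
  pv <- unique(as.character(pred$video_id))
  if (!identical(tv, pv)) {
    rlang::abort(paste0(
      "pairing error: video_id mismatch ('", tv[1L], "' vs '", pv[1L], "')"
    ))
  }
  tibble::tibble(
    video_id = as.character(truth$video_id),
    frame = as.integer(truth$frame),
    truth = truth$label,
    pred = pred$label
  )
}

# Internal: validate a pair tibble.
validate_pair <- function(pair, arg = "pair") {
  if (!is.data.frame(pair) || !all(c("truth", "pred") %in% names(pair))) {
    rlang::abort(paste0("`", arg, "` must be a pair tibble with columns truth, pred"))
  }
  if (nrow(pair) == 0L) {
    rlang::abort(paste0("`", arg, "` has no frames"))
  }
  if (!identical(levels(pair$truth), levels(pair$pred))) {
    rlang::abort(paste0("`", arg, "`: truth and pred use different vocabularies"))
  }
  invisible(pair)
}

# Internal: extract the prediction column of a pair as a sequence tibble.
pair_pred_sequence <- function(pair) {
  tibble::tibble(
    video_id = if ("video_id" %in% names(pair)) as.character(pair$video_id) else "video",
    frame = seq_len(nrow(pair)) - 1L,
    label = pair$pred
  )
}

# Internal: ground-truth column of a pair as a sequence tibble.
pair_truth_sequence <- function(pair) {
  tibble::tibble(
    video_id = if ("video_id" %in% names(pair)) as.character(pair$video_id) else "video",
    frame = seq_len(nrow(pair)) - 1L,
    label = pair$truth
  )
}
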