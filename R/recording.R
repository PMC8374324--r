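#' Construct a labeled heart-sound recording
#'
#' The basic data unit of the package: a mono waveform with its sample rate,
#' a normal/abnormal/unlabeled label, an identifier, and a domain tag (the
#' data-collection source, e.g. a PhysioNet subset letter or a synthetic
#' domain name).
#'
#' @param samples Numeric vector of finite amplitudes.
#' @param rate Sample rate in Hz (> 0); the pipeline expects 2000.
#' @param label One of `"normal"`, `"abnormal"`, `"unlabeled"`.
#' @param recording_id Identifier string.
#' @param domain_id Source/subset tag.
#' @return An object of class `pcg_recording`.
#' @export
pcg_recording <- function(samples, rate, label = "unlabeled",
                          recording_id = "rec", domain_id = "default") {
  samples <- as.numeric(samples)
  if (length(samples) < 1) stop("recording has no samples")
  if (!all(is.finite(samples))) stop("recording contains non-finite samples")
  if (!(is.numeric(rate) && length(rate) == 1 && rate > 0)) {
    stop("rate must be a positive scalar")
  }
  label <- match.arg(label, c("normal", "abnormal", "unlabeled"))
  structure(
    list(samples = samples, rate = rate, label = label,
         recording_id = as.character(recording_id),
         domain_id = as.character(domain_id)),
    class = "pcg_recording"
  )
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording %s> %.2f s at %g Hz, label=%s, domain=%s\n",
              x$recording_id, length(x$samples) / x$rate, x$rate,
              x$label, x$domain_id))
  invisible(x)
}

#' Construct a dataset of recordings
#'
#' @param recordings List of [pcg_recording()] objects.
#' @return Object of class `pcg_dataset` (a list of recordings).
#' @export
pcg_dataset <- function(recordings) {
  if (!length(recordings)) stop("dataset is empty")
  ok <- vapply(recordings, inherits, logical(1), "pcg_recording")
  if (!all(ok)) stop("all elements must be pcg_recording objects")
  ids <- vapply(recordings, `[[`, character(1), "recording_id")
  if (anyDuplicated(ids)) stop("duplicate recording_id values in dataset")
  names(recordings) <- ids
  structure(recordings, class = "pcg_dataset")
}

#' @export
print.pcg_dataset <- function(x, ...) {
  labs <- vapply(x, `[[`, character(1), "label")
  doms <- vapply(x, `[[`, character(1), "domain_id")
  cat(sprintf("<pcg_dataset> %d recordings (%d normal, %d abnormal) in %d domain(s)\n",
              length(x), sum(labs == "normal"), sum(labs == "abnormal"),
              length(unique(doms))))
  invisible(x)
}

#' Extract the label vector of a dataset
#' @param dataset A `pcg_dataset`.
#' @return Character vector of labels, named by recording id.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset, `[[`, character(1), "label")
}

#' Load a labeled WAV dataset with a PhysioNet-2016-style reference CSV
#'
#' The reference CSV has no header and rows `name,code` where code -1 marks a
#' normal and 1 an abnormal recording (the PhysioNet/CinC 2016 dialect).
#' Recordings at other sample rates are resampled to `target_rate` with a
#' polyphase filter.  Rows whose WAV file is missing are skipped with one
#' collective warning.
#'
#' @param audio_dir Directory containing `<name>.wav` files.
#' @param reference_csv Path to the reference CSV.
#' @param domain_id Domain tag assigned to all loaded recordings.
#' @param target_rate Rate to resample to (Hz).
#' @return A [pcg_dataset()].
#' @export
load_labeled_dataset <- function(audio_dir, reference_csv,
                                 domain_id = basename(audio_dir),
                                 target_rate = 2000) {
  if (!file.exists(reference_csv)) stop("reference CSV not found: ", reference_csv)
  ref <- tryCatch(
    utils::read.csv(reference_csv, header = FALSE,
                    col.names = c("name", "code"),
                    colClasses = c("character", "integer")),
    error = function(e) stop("unreadable reference CSV: ", conditionMessage(e))
  )
  if (!all(ref$code %in% c(-1L, 1L))) {
    stop("reference codes must be -1 (normal) or 1 (abnormal)")
  }
  paths <- file.path(audio_dir, paste0(ref$name, ".wav"))
  present <- file.exists(paths)
  if (any(!present)) {
    warning(sum(!present), " recording(s) in the reference CSV have no WAV file; skipped: ",
            paste(utils::head(ref$name[!present], 5), collapse = ", "))
  }
  if (!any(present)) stop("no referenced WAV files found in ", audio_dir)
  recs <- lapply(which(present), function(i) {
    w <- read_wav(paths[i])
    x <- w$samples
    if (w$rate != target_rate) {
      x <- signal::resample(x, p = target_rate, q = w$rate)
    }
    pcg_recording(x, target_rate,
                  label = if (ref$code[i] == -1L) "normal" else "abnormal",
                  recording_id = ref$name[i], domain_id = domain_id)
  })
  pcg_dataset(recs)
}
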