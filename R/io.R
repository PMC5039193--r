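#' Labelled-matrix TSV I/O, EDF reading, and pipeline configuration
#'
#' All on-disk matrices use one plain format: tab-separated UTF-8, optional
#' leading `#key<TAB>value` metadata lines, one header row of column labels,
#' and (when row labels are present) a first column named `.row`. Values are
#' written with 17 significant digits so a write/read round trip is
#' bit-exact for doubles.
#'
#' @name io
NULL

.ROWLAB <- ".row"

#' Write a labelled matrix as TSV
#'
#' @param x numeric matrix; `dimnames` supply row/column labels.
#' @param path output file path.
#' @param meta named list of scalar metadata written as `#key<TAB>value`
#'   comment lines (e.g. `sampling_rate`).
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(x, path, meta = list()) {
  stopifnot(is.matrix(x))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("#%s\t%s", k, format(meta[[k]], digits = 17)), con)
  }
  cl <- colnames(x)
  if (is.null(cl)) cl <- paste0("V", seq_len(ncol(x)))
  has_rows <- !is.null(rownames(x))
  header <- if (has_rows) c(.ROWLAB, cl) else cl
  writeLines(paste(header, collapse = "\t"), con)
  body <- apply(x, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  if (has_rows) body <- paste(rownames(x), body, sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a labelled matrix from TSV
#'
#' @param path file written by [write_labeled_matrix()] (or any TSV with a
#'   header row).
#' @return numeric matrix with `dimnames` and a `meta` attribute (named list
#'   of the `#` header lines, numbers coerced where possible).
#' @export
read_labeled_matrix <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, encoding = "UTF-8")
  meta <- list()
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- strsplit(sub("^#", "", lines[i]), "\t", fixed = TRUE)[[1]]
    val <- if (length(kv) > 1L) kv[2] else ""
    num <- suppressWarnings(as.numeric(val))
    meta[[kv[1]]] <- if (!is.na(num)) num else val
    i <- i + 1L
  }
  if (i > length(lines)) stop("parse error in '", path, "': no header row")
  header <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(i)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("parse error in '", path, "': no data rows")
  cells <- strsplit(body, "\t", fixed = TRUE)
  nfld <- lengths(cells)
  if (any(nfld != length(header))) {
    bad <- which(nfld != length(header))[1]
    stop("parse error in '", path, "': row ", bad, " has ", nfld[bad],
         " fields, expected ", length(header))
  }
  has_rows <- header[1] == .ROWLAB
  rl <- NULL
  if (has_rows) {
    rl <- vapply(cells, `[`, "", 1L)
    cells <- lapply(cells, `[`, -1L)
    header <- header[-1]
  }
  x <- matrix(as.numeric(unlist(cells, use.names = FALSE)),
              nrow = length(cells), byrow = TRUE,
              dimnames = list(rl, header))
  if (anyNA(x)) stop("parse error in '", path, "': non-numeric cell")
  attr(x, "meta") <- meta
  x
}

#' Read multichannel EEG
#'
#' Returns a channel-major matrix (channels x samples). Delimited input is
#' stored sample-major (rows = samples, header = channel labels) and is
#' transposed on read; the sampling rate must be present as a
#' `#sampling_rate` metadata line or given via `sampling_rate`.
#'
#' @param path EDF file or TSV as above.
#' @param format `"auto"` (sniff the EDF magic), `"edf"` or `"tsv"`.
#' @param sampling_rate overrides/supplies the sampling rate in Hz for TSV
#'   input.
#' @return matrix channels x samples with rownames = channel labels and a
#'   `meta` attribute carrying `sampling_rate`.
#' @export
read_eeg <- function(path, format = c("auto", "edf", "tsv"),
                     sampling_rate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "auto") {
    hd <- readBin(path, "raw", n = 8L)
    format <- if (rawToChar(hd) == "0       ") "edf" else "tsv"
  }
  if (format == "edf") return(read_edf(path))
  m <- read_labeled_matrix(path)
  meta <- attr(m, "meta")
  fs <- if (!is.null(sampling_rate)) sampling_rate else meta$sampling_rate
  if (is.null(fs)) {
    stop("config error: missing 'sampling_rate' for delimited EEG input '",
         path, "'")
  }
  x <- t(m)
  attr(x, "meta") <- utils::modifyList(meta, list(sampling_rate = fs))
  x
}

#' Read fMRI independent-component time courses
#'
#' @param path TSV with a header row of component labels; one row per TR.
#' @return matrix time x components; row count is the TR count.
#' @export
read_timecourses <- function(path) {
  read_labeled_matrix(path)
}

# ---- minimal EDF (European Data Format, 16-bit) ------------------------

.edf_field <- function(raw, at, len) {
  trimws(rawToChar(raw[(at + 1L):(at + len)]))
}

#' Read a 16-bit EDF file
#'
#' Minimal reader for continuous EDF recordings in which every signal shares
#' one sampling rate (mixed per-signal rates are rejected: band-power
#' epoching needs a single time base).
#'
#' @param path EDF file.
#' @return matrix channels x samples (physical units), rownames = channel
#'   labels, `meta` attribute with `sampling_rate`.
#' @export
read_edf <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 256L || rawToChar(raw[1:8]) != "0       ") {
    stop("cannot read '", path, "': not an EDF file")
  }
  n_rec <- as.integer(.edf_field(raw, 236L, 8L))
  dur <- as.numeric(.edf_field(raw, 244L, 8L))
  ns <- as.integer(.edf_field(raw, 252L, 4L))
  off <- 256L
  fld <- function(w) { # ns consecutive fields of width w
    out <- vapply(seq_len(ns) - 1L, function(i) .edf_field(raw, off + i * w, w), "")
    off <<- off + ns * w
    out
  }
  labels <- fld(16L)
  off <- off + ns * (80L + 8L)              # transducer, physical dimension
  phys_min <- as.numeric(fld(8L))
  phys_max <- as.numeric(fld(8L))
  dig_min <- as.numeric(fld(8L))
  dig_max <- as.numeric(fld(8L))
  off <- off + ns * 80L                     # prefiltering
  nsamp <- as.integer(fld(8L))
  off <- off + ns * 32L                     # reserved
  if (length(unique(nsamp)) != 1L) {
    bad <- labels[nsamp != max(nsamp)]
    stop("EDF '", path, "': mixed per-signal sampling rates; offending ",
         "channels: ", paste(bad, collapse = ", "))
  }
  spr <- nsamp[1]
  vals <- readBin(raw[(off + 1L):length(raw)], "integer", size = 2L,
                  n = n_rec * ns * spr, endian = "little")
  x <- matrix(0, nrow = ns, ncol = n_rec * spr, dimnames = list(labels, NULL))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    block <- matrix(vals[((r - 1L) * ns * spr + 1L):(r * ns * spr)],
                    nrow = spr, ncol = ns)
    x[, ((r - 1L) * spr + 1L):(r * spr)] <-
      t(block) * gain + (phys_min - dig_min * gain)
  }
  attr(x, "meta") <- list(sampling_rate = spr / dur)
  x
}

#' Write a 16-bit EDF file
#'
#' Companion writer used by the simulator and tests; one data record per
#' second, all signals at the same rate.
#'
#' @param x matrix channels x samples (physical units).
#' @param path output path.
#' @param sampling_rate samples per second (record duration is 1 s, so the
#'   sample count per channel must be a multiple of it).
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, path, sampling_rate) {
  stopifnot(is.matrix(x), ncol(x) %% sampling_rate == 0)
  ns <- nrow(x)
  n_rec <- ncol(x) / sampling_rate
  labels <- rownames(x)
  if (is.null(labels)) labels <- paste0("CH", seq_len(ns))
  # physical limits rounded outward to the 2 decimals the header stores,
  # so writer and reader use identical scaling
  pmin <- floor(apply(x, 1L, min) * 100) / 100
  pmax <- ceiling(apply(x, 1L, max) * 100) / 100
  same <- pmax - pmin < 0.01
  pmax[same] <- pmin[same] + 1
  f <- function(v, w) {
    s <- substr(formatC(as.character(v), width = -1), 1L, w)
    sprintf("%-*s", w, s)
  }
  hdr <- paste0(
    f("0", 8L), f("synthetic", 80L), f("synthetic", 80L),
    f("01.01.26", 8L), f("00.00.00", 8L),
    f(256L * (1L + ns), 8L), f("", 44L), f(n_rec, 8L), f(1, 8L), f(ns, 4L),
    paste(f(labels, 16L), collapse = ""),
    paste(rep(f("", 80L), ns), collapse = ""),
    paste(rep(f("uV", 8L), ns), collapse = ""),
    paste(f(sprintf("%.2f", pmin), 8L), collapse = ""),
    paste(f(sprintf("%.2f", pmax), 8L), collapse = ""),
    paste(rep(f(-32768L, 8L), ns), collapse = ""),
    paste(rep(f(32767L, 8L), ns), collapse = ""),
    paste(rep(f("", 80L), ns), collapse = ""),
    paste(rep(f(sampling_rate, 8L), ns), collapse = ""),
    paste(rep(f("", 32L), ns), collapse = "")
  )
  gain <- (pmax - pmin) / 65535
  dig <- round((x - pmin) / gain - 32768)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * sampling_rate + 1L):(r * sampling_rate)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

# ---- pipeline configuration --------------------------------------------

#' Pipeline configuration
#'
#' Central parameter object shared by every stage. Defaults reproduce the
#' reference configuration: TR = 2 s, 2-s epochs, five EEG bands (delta
#' 1-4 Hz, theta 4-8, alpha 8-13, beta 13-30, low gamma 30-35), sliding
#' windows of 20 TRs in steps of 1 TR, IC band-pass 0.01-0.10 Hz,
#' low-frequency-amplitude band (0, 0.025] Hz, nodal FDR level q = 0.001.
#'
#' @param tr_seconds fMRI repetition time in seconds.
#' @param epoch_seconds EEG epoch length in seconds (one epoch per TR).
#' @param bands named list of `c(low, high)` Hz pairs, in band order.
#' @param window_length_tr sliding-window width in TRs (>= 2).
#' @param window_step_tr window step in TRs (>= 1).
#' @param lfa_band_hz low-frequency amplitude band (Hz), DC excluded.
#' @param bandpass_hz IC time-course band-pass (Hz).
#' @param fdr_q FDR level for nodal tests.
#' @param rng_seed integer seed recorded in manifests.
#' @param eeg_fs EEG sampling rate in Hz (needed to check band validity;
#'   `NULL` defers the Nyquist check to use time).
#' @return object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(tr_seconds = 2, epoch_seconds = 2,
                            bands = list(delta = c(1, 4), theta = c(4, 8),
                                         alpha = c(8, 13), beta = c(13, 30),
                                         low_gamma = c(30, 35)),
                            window_length_tr = 20L, window_step_tr = 1L,
                            lfa_band_hz = c(0, 0.025),
                            bandpass_hz = c(0.01, 0.10),
                            fdr_q = 0.001, rng_seed = 1L, eeg_fs = NULL) {
  stopifnot(tr_seconds > 0, epoch_seconds > 0,
            window_length_tr >= 2, window_step_tr >= 1,
            fdr_q > 0, fdr_q < 1, length(bandpass_hz) == 2,
            bandpass_hz[1] > 0, bandpass_hz[2] > bandpass_hz[1])
  if (length(bands) == 0L) stop("config error: empty band list")
  for (b in names(bands)) {
    bb <- bands[[b]]
    if (length(bb) != 2 || bb[1] <= 0 || bb[2] <= bb[1]) {
      stop("config error: band '", b, "' must be (low, high) with 0 < low < high")
    }
    if (!is.null(eeg_fs) && bb[2] > eeg_fs / 2) {
      stop("config error: band '", b, "' exceeds Nyquist ", eeg_fs / 2, " Hz")
    }
  }
  structure(list(tr_seconds = tr_seconds, epoch_seconds = epoch_seconds,
                 bands = bands,
                 window_length_tr = as.integer(window_length_tr),
                 window_step_tr = as.integer(window_step_tr),
                 lfa_band_hz = lfa_band_hz, bandpass_hz = bandpass_hz,
                 fdr_q = fdr_q, rng_seed = as.integer(rng_seed),
                 eeg_fs = eeg_fs),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipeline_config()] arguments; `bands` is a mapping from band
#' name to `[low, high]`. Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file.
#' @return `pipeline_config` object.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("config error: unknown key(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$bands)) y$bands <- lapply(y$bands, as.numeric)
  do.call(pipeline_config, y)
}

#' Write a run manifest
#'
#' Records the configuration, seed, and an md5 digest of every input file so
#' a multi-stage run is auditable and exactly repeatable.
#'
#' @param dir output directory.
#' @param config `pipeline_config`.
#' @param inputs character vector of input file paths.
#' @param extra named list of additional fields (e.g. the subcommand).
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, inputs = character(), extra = list()) {
  digests <- if (length(inputs)) {
    stats::setNames(as.list(unname(tools::md5sum(inputs))), basename(inputs))
  } else list()
  man <- c(list(config = unclass(config), seed = config$rng_seed,
                input_md5 = digests), extra)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}
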