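#' Encode a per-channel level vector as a sweep index
#'
#' Mixed-radix bijection over the canonical channel ordering: the index is
#' sum(level_c * 4^position(c)), positions 0-based, so the first channel
#' of the ordering is the least significant digit. Levels are integer
#' codes 0:3 mapping to the factors 0.25, 0.50, 0.75, 1.00.
#'
#' @param levels Integer vector of level codes in `0:(n_levels-1)`, named
#'   by channel or given in the `channels` order.
#' @param channels Channel subset (canonical order), default all ten.
#' @param n_levels Radix (default 4).
#' @return Integer (double for the full 4^10 range) case index.
#' @export
#' @examples
#' encodeIndex(rep(3L, 10)) # == 4^10 - 1
encodeIndex <- function(levels, channels = channelIds(), n_levels = 4L) {
  if (!is.null(names(levels))) levels <- levels[channels]
  stopifnot(length(levels) == length(channels),
            all(levels >= 0), all(levels < n_levels),
            all(levels == floor(levels)))
  sum(as.numeric(levels) * n_levels^(seq_along(channels) - 1))
}

#' @rdname encodeIndex
#' @param index Case index as produced by `encodeIndex`.
#' @export
decodeIndex <- function(index, channels = channelIds(), n_levels = 4L) {
  stopifnot(index >= 0, index < n_levels^length(channels))
  out <- integer(length(channels))
  x <- as.numeric(index)
  for (k in seq_along(channels)) {
    out[k] <- as.integer(x %% n_levels)
    x <- x %/% n_levels
  }
  names(out) <- channels
  out
}

levelToFactor <- function(level, levels = sweepLevels()) {
  levels[level + 1L]
}

#' Enumerate the factorial conductance population
#'
#' Yields all `|levels|^|channels|` cases of the factorial sweep in
#' ascending index order. Channels not listed are fixed at factor 1.
#'
#' @param channels Channel subset (in canonical order), default all ten.
#' @param levels Conductance factors per level, default
#'   `sweepLevels()` (25-100%).
#' @return A `sweep_enum`: list with `index` (case indices), `levels`
#'   (n x length(channels) integer matrix of level codes), `channels`,
#'   `factors`.
#' @export
#' @examples
#' e <- enumerateScalings(c("CaL", "Ks"))
#' nrow(e$levels) # 16
enumerateScalings <- function(channels = channelIds(),
                              levels = sweepLevels()) {
  stopifnot(length(channels) >= 1, all(channels %in% channelIds()),
            !anyDuplicated(channels), length(levels) >= 1)
  channels <- channelIds()[channelIds() %in% channels] # canonical order
  nl <- length(levels)
  grid <- expand.grid(rep(list(seq_len(nl) - 1L), length(channels)),
                      KEEP.OUT.ATTRS = FALSE)
  lev <- as.matrix(grid)
  dimnames(lev) <- list(NULL, channels)
  idx <- as.numeric(lev %*% nl^(seq_along(channels) - 1))
  out <- list(index = idx, levels = lev, channels = channels,
              factors = levels)
  class(out) <- "sweep_enum"
  out
}

#' @export
print.sweep_enum <- function(x, ...) {
  cat("<sweep_enum>", nrow(x$levels), "cases over",
      length(x$channels), "channels (",
      paste(x$channels, collapse = ", "), ") at levels",
      paste(x$factors, collapse = "/"), "\n")
  invisible(x)
}

#' Scaling vector for one enumerated case
#'
#' @param enum A `sweep_enum` from [enumerateScalings()].
#' @param i Row number (1-based position in the enumeration).
#' @return Named length-10 scaling vector (non-swept channels at 1).
#' @export
scalingForCase <- function(enum, i) {
  f <- setNames(rep(1, 10), channelIds())
  f[enum$channels] <- enum$factors[enum$levels[i, ] + 1L]
  f
}

sweepMetadata <- function(enum, config) {
  cfg <- paste(vapply(config, function(x) paste(format(x), collapse = ";"),
                      character(1)), collapse = "|")
  hash <- sum(utf8ToInt(cfg) * seq_along(utf8ToInt(cfg))) %% 2147483647
  c(sprintf("# channels: %s", paste(enum$channels, collapse = ",")),
    sprintf("# factors: %s", paste(enum$factors, collapse = ",")),
    sprintf("# config_hash: %d", hash))
}

readCheckpoint <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) return(NULL)
  df <- tryCatch(read.csv(path, comment.char = "#"),
                 error = function(e) NULL)
  if (is.null(df) || !nrow(df)) return(NULL)
  df
}

#' Execute a conductance-population sweep
#'
#' Runs the per-case protocol for every enumerated case at every basic
#' cycle length, producing the canonical results table (one biomarker
#' record per case x BCL). With a checkpoint path, rows are appended as
#' they complete and a restart skips already-completed (case, BCL) keys,
#' so an interrupted sweep resumes without recomputation. Per-case
#' failures are recorded in the `diverged` flag, never fatal.
#'
#' @param enum A `sweep_enum` from [enumerateScalings()].
#' @param bcls Numeric vector of basic cycle lengths (ms).
#' @param config Protocol settings, see [epConfig()].
#' @param mech_params See [mechParameters()].
#' @param checkpoint Optional CSV path for resumable execution.
#' @param runner Per-case function with the signature of [runCase()];
#'   replaceable by a surrogate for testing the sweep machinery.
#' @param max_cases Optional cap on the number of enumerated cases run.
#' @param quiet Suppress the summary message.
#' @return The results table: a data.frame of biomarker records sorted by
#'   (bcl_ms, case_id), with attributes `channels` and `factors`.
#' @export
runSweep <- function(enum, bcls, config = epConfig(),
                     mech_params = mechParameters(), checkpoint = NULL,
                     runner = runCase, max_cases = Inf, quiet = FALSE) {
  stopifnot(inherits(enum, "sweep_enum"), length(bcls) >= 1)
  done <- NULL
  if (!is.null(checkpoint)) {
    dir.create(dirname(checkpoint), recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dirname(checkpoint)))
      stop("checkpoint location is not writable: ", checkpoint)
    done <- readCheckpoint(checkpoint)
    if (is.null(done) || !nrow(done)) {
      writeLines(c(sweepMetadata(enum, config),
                   paste(biomarkerColumns(), collapse = ",")), checkpoint)
      done <- NULL
    }
  }
  donekeys <- if (is.null(done)) character(0) else
    paste(done$case_id, done$bcl_ms)

  n <- min(nrow(enum$levels), max_cases)
  rows <- if (is.null(done)) list() else list(done)
  for (i in seq_len(n)) {
    sc <- scalingForCase(enum, i)
    for (bcl in bcls) {
      key <- paste(enum$index[i], bcl)
      if (key %in% donekeys) next
      rec <- runner(sc, bcl = bcl, config = config,
                    mech_params = mech_params, case_id = enum$index[i])
      rows[[length(rows) + 1L]] <- rec
      if (!is.null(checkpoint)) {
        line <- paste(vapply(rec[1, biomarkerColumns()], function(x)
          if (is.na(x)) "NA" else format(x, digits = 15),
          character(1)), collapse = ",")
        cat(line, "\n", sep = "", file = checkpoint, append = TRUE)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else emptyRecord(1, 1)[0, ]
  tab <- tab[order(tab$bcl_ms, tab$case_id), , drop = FALSE]
  rownames(tab) <- NULL
  if (anyDuplicated(paste(tab$case_id, tab$bcl_ms)))
    stop("duplicate (case, bcl) keys in results table")
  attr(tab, "channels") <- enum$channels
  attr(tab, "factors") <- enum$factors
  if (!quiet)
    message(sprintf(
      "sweep: %d records; %d contracted, %d no-contraction, %d diverged",
      nrow(tab), sum(tab$contracted), sum(!tab$contracted & !tab$diverged),
      sum(tab$diverged)))
  tab
}

#' Read a results table written by [runSweep()]
#'
#' Restores the `channels`/`factors` attributes from the metadata header.
#'
#' @param path CSV path.
#' @return The results table data.frame.
#' @export
readResultsTable <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  tab <- read.csv(path, comment.char = "#")
  getmeta <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    if (!length(ln)) return(NULL)
    strsplit(sub(paste0("^# ", key, ": *"), "", ln[1]), ",")[[1]]
  }
  ch <- getmeta("channels")
  if (!is.null(ch)) attr(tab, "channels") <- ch
  fa <- getmeta("factors")
  if (!is.null(fa)) attr(tab, "factors") <- as.numeric(fa)
  tab
}

#' Write a results table with its metadata header
#'
#' @param tab Results table from [runSweep()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeResultsTable <- function(tab, path) {
  enum <- list(channels = attr(tab, "channels"),
               factors = attr(tab, "factors"))
  writeLines(c(sprintf("# channels: %s",
                       paste(enum$channels, collapse = ",")),
               sprintf("# factors: %s",
                       paste(enum$factors, collapse = ","))), path)
  suppressWarnings(
    write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE,
                append = TRUE))
  invisible(path)
}
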