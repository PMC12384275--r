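# Task trimming and analysis-window generation. The first and last 15 s of
# every task are discarded (transition artifacts); HR uses 15 s windows with
# 50% overlap, BR splits the trimmed 90 s paced-breathing span into two 45 s
# windows, one per paced rate.

#' Trim the transition edges off a task span
#'
#' @param start_s,end_s Task boundaries, seconds.
#' @param trim_s Seconds removed from each end (default 15).
#' @return Numeric `c(start, end)` of the usable span.
#' @export
trim_task <- function(start_s, end_s, trim_s = 15) {
  if (end_s - start_s <= 2 * trim_s)
    stop(sprintf("task span of %.1f s leaves no usable signal after trimming %g s per end",
                 end_s - start_s, trim_s))
  c(start_s + trim_s, end_s - trim_s)
}

#' Sliding HR analysis windows over a span
#'
#' Window starts form the arithmetic progression 0, `win_s * (1 - overlap)`,
#' ... while the full window fits; a trailing partial window is dropped. A
#' trimmed two-minute task (90 s usable) yields 11 windows.
#'
#' @param start_s,end_s Usable span, seconds.
#' @param win_s Window length, seconds.
#' @param overlap Fractional overlap in [0, 1).
#' @return data.frame with `index`, `start_s`, `end_s`; zero rows if the span
#'   is shorter than one window.
#' @export
hr_windows <- function(start_s, end_s, win_s = 15, overlap = 0.5) {
  stopifnot(win_s > 0, overlap >= 0, overlap < 1)
  L <- end_s - start_s
  if (L < win_s)
    return(data.frame(index = integer(0), start_s = numeric(0),
                      end_s = numeric(0)))
  step <- win_s * (1 - overlap)
  k <- floor((L - win_s) / step + 1e-9)
  starts <- start_s + step * (0:k)
  data.frame(index = seq_len(k + 1L), start_s = starts,
             end_s = starts + win_s)
}

#' Split a trimmed paced-breathing span into two labelled 45 s windows
#'
#' The paced task runs one minute per target rate; after trimming 15 s per
#' end the 90 s that remain split exactly at the rate switch.
#'
#' @param start_s,end_s Trimmed span (must be 90 s unless `flex = TRUE`).
#' @param labels Nominal breathing rates of the two halves, breaths/min.
#' @param flex Allow proportional splitting of a span that is not 90 s.
#' @return data.frame with `index`, `start_s`, `end_s`, `br_label`.
#' @export
br_windows <- function(start_s, end_s, labels = c(6, 10), flex = FALSE) {
  L <- end_s - start_s
  if (!flex && abs(L - 90) > 1e-9)
    stop("paced-breathing span must be 90 s after trimming (use flex = TRUE to split proportionally)")
  mid <- start_s + L / 2
  data.frame(index = 1:2, start_s = c(start_s, mid), end_s = c(mid, end_s),
             br_label = labels)
}

# Slice a channel by time using half-open sample indexing [start, end);
# the sample count is exactly round(win_s * fs) regardless of channel rate.
slice_window <- function(x, fs, start_s, end_s) {
  i0 <- round(start_s * fs) + 1L
  i1 <- round(end_s * fs)
  x[i0:min(i1, length(x))]
}
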