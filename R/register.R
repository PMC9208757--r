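#' Estimate global XY drift of a time-lapse stack
#'
#' Automated translation registration: each consecutive frame pair is
#' aligned by the peak of their (mean-subtracted, FFT-based circular)
#' cross-correlation, refined to sub-pixel precision by a local quadratic
#' fit of the correlation peak (tie-broken toward zero shift), and the
#' pairwise shifts are composed into a cumulative drift series anchored at
#' the reference frame. Consecutive-pair estimation is robust to the slow
#' content change of long movies, unlike all-to-reference matching.
#'
#' On content that is a pure translation of the reference the recovered
#' shift is within 0.5 px. A frame with zero intensity variance cannot be
#' registered; it inherits the previous frame's drift with a warning.
#'
#' @param stack an \code{\link{image_stack}} with >= 2 frames.
#' @param channel channel index or name used for registration (typically a
#'   channel dominated by static background structures, e.g. nuclei).
#' @param reference_frame 0-based frame whose drift is defined as (0, 0).
#' @return data frame of class \code{drift_series} with columns
#'   \code{frame}, \code{dx_px}, \code{dy_px}, \code{dx_um}, \code{dy_um}:
#'   the cumulative translation of each frame's content relative to the
#'   reference frame.
#' @export
estimate_drift <- function(stack, channel = 1, reference_frame = 0L) {
  nf <- n_frames(stack)
  if (nf < 2L) stop("drift estimation needs >= 2 frames")
  if (reference_frame < 0L || reference_frame >= nf)
    stop("reference_frame out of range")
  pair <- matrix(0, nf, 2)  # shift of frame t relative to frame t-1
  prev <- get_frame(stack, 0L, channel)
  prev_f <- NULL
  for (t in seq_len(nf - 1)) {
    cur <- get_frame(stack, t, channel)
    if (stats::var(as.vector(cur)) < .Machine$double.eps ||
        stats::var(as.vector(prev)) < .Machine$double.eps) {
      warning("frame ", t, " (or its predecessor) is flat; inheriting ",
              "previous drift")
      pair[t + 1, ] <- c(0, 0)
    } else {
      pair[t + 1, ] <- xcorr_shift(prev, cur)
    }
    prev <- cur
  }
  cum <- apply(pair, 2, cumsum)
  cum <- sweep(cum, 2, cum[reference_frame + 1L, ])
  structure(data.frame(frame = 0:(nf - 1),
                       dx_px = cum[, 1], dy_px = cum[, 2],
                       dx_um = cum[, 1] * stack$pixel_size_um,
                       dy_um = cum[, 2] * stack$pixel_size_um),
            reference_frame = as.integer(reference_frame),
            pixel_size_um = stack$pixel_size_um,
            class = c("drift_series", "data.frame"))
}

# shift (dx, dy) maximizing circular cross-correlation of b against a:
# b approx a translated by (dx, dy). Integer peak first, then sub-pixel
# refinement by evaluating the correlation on a local 0.05 px grid through
# the cross-power spectrum (matrix-multiply DFT), followed by a quadratic
# fit of the fine-grid peak; ties broken toward zero shift.
xcorr_shift <- function(a, b) {
  # Hann window: suppresses wrap-around artifacts and the bias from
  # structures truncated at the field border
  han <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  w <- outer(han(nrow(a)), han(ncol(a)))
  a <- (a - mean(a)) * w; b <- (b - mean(b)) * w
  fa <- stats::fft(a); fb <- stats::fft(b)
  R <- fb * Conj(fa)
  cc <- Re(stats::fft(R, inverse = TRUE))
  nr <- nrow(cc); nc <- ncol(cc)
  pk <- which(cc == max(cc), arr.ind = TRUE)
  wrap <- function(k, n) ifelse(k > n / 2, k - n, k)
  if (nrow(pk) > 1) {  # tie-break toward zero shift
    wr <- wrap(pk[, 1] - 1, nr); wc <- wrap(pk[, 2] - 1, nc)
    pk <- pk[which.min(wr^2 + wc^2), , drop = FALSE]
  }
  s_r0 <- wrap(pk[1, 1] - 1, nr); s_c0 <- wrap(pk[1, 2] - 1, nc)
  # signed spatial frequencies
  kr <- wrap(0:(nr - 1), nr); kc <- wrap(0:(nc - 1), nc)
  step <- 0.05
  gr <- s_r0 + seq(-1, 1, by = step); gc <- s_c0 + seq(-1, 1, by = step)
  A <- exp(2i * pi * outer(gr, kr / nr))            # grid x row freq
  B <- exp(2i * pi * outer(kc / nc, gc))            # col freq x grid
  C <- Re(A %*% R %*% B)
  fp <- which(C == max(C), arr.ind = TRUE)[1, , drop = TRUE]
  # quadratic interpolation on the fine grid
  quad <- function(i, n, vals) {
    if (i <= 1 || i >= n) return(0)
    den <- vals[i - 1] - 2 * vals[i] + vals[i + 1]
    if (abs(den) < .Machine$double.eps) 0 else
      clamp(0.5 * (vals[i - 1] - vals[i + 1]) / den, -1, 1)
  }
  dr <- quad(fp[1], length(gr), C[, fp[2]]) * step
  dc <- quad(fp[2], length(gc), C[fp[1], ]) * step
  c(dx = gc[fp[2]] + dc, dy = gr[fp[1]] + dr)
}

#' Apply a drift correction to a stack or to point tracks
#'
#' Stacks are resampled by the inverse translation (bilinear interpolation,
#' constant-zero padding outside the field); point tracks are shifted
#' exactly, with no interpolation, so correcting a track with the drift
#' used to corrupt it recovers the original to machine precision.
#'
#' @param target an \code{\link{image_stack}} or a \code{point_tracks}
#'   data frame.
#' @param drift a \code{drift_series} from \code{\link{estimate_drift}}
#'   (or a data frame with columns frame, dx_um, dy_um; for stacks also
#'   dx_px, dy_px).
#' @return the corrected target, same class as the input.
#' @export
apply_drift_correction <- function(target, drift) {
  if (inherits(target, "image_stack")) {
    nf <- n_frames(target)
    if (!all((0:(nf - 1)) %in% drift$frame))
      stop("drift series does not cover all stack frames")
    d <- dim(target$pixels)
    out <- target$pixels
    for (t in seq_len(nf)) {
      i <- which(drift$frame == t - 1L)
      dx <- drift$dx_px[i]; dy <- drift$dy_px[i]
      if (abs(dx) < 1e-12 && abs(dy) < 1e-12) next
      if (target$has_z) {
        for (z in seq_len(d[3])) for (ch in seq_len(d[4]))
          out[, , z, ch, t] <- translate_image(target$pixels[, , z, ch, t], -dx, -dy)
      } else {
        for (ch in seq_len(d[3]))
          out[, , ch, t] <- translate_image(target$pixels[, , ch, t], -dx, -dy)
      }
    }
    target$pixels <- out
    target
  } else if (inherits(target, "point_tracks") || is.data.frame(target)) {
    i <- match(target$frame, drift$frame)
    if (anyNA(i))
      stop("frame(s) outside drift domain: ",
           paste(unique(target$frame[is.na(i)]), collapse = ", "))
    target$x_um <- target$x_um - drift$dx_um[i]
    target$y_um <- target$y_um - drift$dy_um[i]
    target
  } else stop("target must be an image_stack or point_tracks")
}
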