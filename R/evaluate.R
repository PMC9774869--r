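#' Image-domain evaluation of a denoised stack against a clean reference
#'
#' Reconstructs the selected frames of both stacks with the same
#' delay-and-sum beamformer, envelope-detects them, and computes the
#' reference metrics (PSNR, SSIM, EPI) per frame.
#'
#' @param stack Denoised (or noisy) [rf_stack()].
#' @param reference Clean [rf_stack()] of identical shape.
#' @param prep [das_prepare()] tables; built from `grid` when `NULL`.
#' @param grid An [image_grid()] (used only when `prep` is `NULL`;
#'   defaults to the standard evaluation grid).
#' @param frames Frames to evaluate (default: all).
#' @param reference_images Optionally, precomputed envelope images of the
#'   reference for these frames (3-D array), to avoid re-reconstruction
#'   across repeated calls.
#' @return `data.frame` with columns `frame`, `psnr`, `ssim`, `epi`.
#' @export
evaluate_denoising <- function(stack, reference, prep = NULL, grid = NULL,
                               frames = NULL, reference_images = NULL) {
  stopifnot(is_rf_stack(stack), is_rf_stack(reference))
  if (!all(dim(stack$samples) == dim(reference$samples))) {
    stop("stack and reference must have identical shape")
  }
  if (is.null(frames)) frames <- seq_len(n_frames(stack))
  if (is.null(prep)) {
    if (is.null(grid)) grid <- image_grid(stack$geometry,
                                          z_range_mm = c(8, 23),
                                          dz_mm = 0.15)
    prep <- das_prepare(stack$geometry, grid, dim(stack$samples)[2])
  }
  ref <- if (is.null(reference_images)) {
    reconstruct_stack(reference, prep, frames)
  } else reference_images
  den <- reconstruct_stack(stack, prep, frames)
  rows <- lapply(seq_along(frames), function(i) {
    data.frame(frame = frames[i],
               psnr = pa_psnr(den[, , i], ref[, , i]),
               ssim = pa_ssim(den[, , i], ref[, , i]),
               epi = pa_epi(den[, , i], ref[, , i]))
  })
  do.call(rbind, rows)
}

#' Sweep the retained singular-component count
#'
#' Denoises `noisy` with the spatiotemporal SVD pipeline for each k in
#' `ks` and evaluates each result against `clean`, reporting per-k mean
#' metrics. This reproduces the quality-vs-SVC analysis used to study
#' rank selection.
#'
#' @param noisy,clean [rf_stack()] pair.
#' @param ks Integer vector of retained-component counts.
#' @param window_frames Sliding-window length.
#' @param frames Frames over which metrics are averaged (default: all).
#' @param seed Seed for the pipeline.
#' @param prep,grid See [evaluate_denoising()].
#' @return `data.frame` with one row per k: `k`, `psnr`, `ssim`, `epi`.
#' @export
svc_sweep <- function(noisy, clean, ks = 1:7, window_frames = 75L,
                      frames = NULL, seed = 1L, prep = NULL, grid = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(noisy))
  if (is.null(prep)) {
    if (is.null(grid)) grid <- image_grid(noisy$geometry,
                                          z_range_mm = c(8, 23),
                                          dz_mm = 0.15)
    prep <- das_prepare(noisy$geometry, grid, dim(noisy$samples)[2])
  }
  ref <- reconstruct_stack(clean, prep, frames)
  rows <- lapply(ks, function(k) {
    den <- stsvd_denoise(noisy, denoise_config(rank = k,
                                               window_frames = window_frames,
                                               seed = seed))
    m <- evaluate_denoising(den$stack, clean, prep = prep, frames = frames,
                            reference_images = ref)
    data.frame(k = k, psnr = mean(m$psnr), ssim = mean(m$ssim),
               epi = mean(m$epi))
  })
  do.call(rbind, rows)
}

#' Sweep the averaging/decomposition batch size
#'
#' Compares frame averaging and the spatiotemporal SVD pipeline over a set
#' of batch (window) sizes against a clean reference.
#'
#' @inheritParams svc_sweep
#' @param batches Batch sizes (window lengths).
#' @param rank Rank setting for the SVD pipeline (default `"auto-min"`).
#' @return `data.frame` with columns `batch`, `method`, `psnr`, `ssim`,
#'   `epi`.
#' @export
batch_sweep <- function(noisy, clean, batches = c(5, 10, 25, 50, 75, 100),
                        rank = "auto-min", frames = NULL, seed = 1L,
                        prep = NULL, grid = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(noisy))
  if (is.null(prep)) {
    if (is.null(grid)) grid <- image_grid(noisy$geometry,
                                          z_range_mm = c(8, 23),
                                          dz_mm = 0.15)
    prep <- das_prepare(noisy$geometry, grid, dim(noisy$samples)[2])
  }
  ref <- reconstruct_stack(clean, prep, frames)
  rows <- lapply(batches, function(b) {
    avg <- frame_average(noisy, b)
    ma <- evaluate_denoising(avg, clean, prep = prep, frames = frames,
                             reference_images = ref)
    r <- if (is.character(rank) && b < 8L) 1L else rank  # tiny windows: fixed
    den <- stsvd_denoise(noisy, denoise_config(rank = r, window_frames = b,
                                               seed = seed))
    ms <- evaluate_denoising(den$stack, clean, prep = prep, frames = frames,
                             reference_images = ref)
    rbind(data.frame(batch = b, method = "average", psnr = mean(ma$psnr),
                     ssim = mean(ma$ssim), epi = mean(ma$epi)),
          data.frame(batch = b, method = "stsvd", psnr = mean(ms$psnr),
                     ssim = mean(ms$ssim), epi = mean(ms$epi)))
  })
  do.call(rbind, rows)
}
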