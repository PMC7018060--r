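#' Simulate QCT phantom observations
#'
#' Generates phantom-region ROI mean CT numbers obeying the calibration model
#' `CT# = B_r - A_r ln(size) + N(0, sigma)` over a cohort of slice sizes, for
#' the four phantom regions P1-P4 (nominal 0, 50, 100, 200 mg/ml calcium
#' hydroxyapatite). Sizes are drawn log-uniformly over `size_range`, the
#' realistic TSI span for a small-primate cohort; a CSA column coupled to the
#' TSI through a proportional relationship with log-normal noise is included
#' so that index-comparison analyses have both candidates. Defaults place the
#' water-equivalent P1 region at B = 60 HU with a slope large enough that
#' subject size masks tissue contrast when uncorrected, A and B growing with
#' phantom density as denser material hardens the beam more strongly; the
#' near-identical P1/P2 slopes reflect the soft-tissue density band whose
#' pooled slope drives the correction.
#'
#' @param n_per_region observations (slices) per region; default 18.
#' @param size_range TSI range the sizes are drawn from; default `c(2, 9)`.
#' @param B,A numeric length-4 (or recycled) true intercepts and slopes for
#'   P1-P4.
#' @param noise_sd HU noise SD; default 1.
#' @param csa_scale multiplicative TSI -> CSA factor (mm^2 per TSI unit).
#' @param csa_log_noise SD of the log-normal noise decoupling CSA from TSI;
#'   0 makes the two indices perfectly equivalent.
#' @param regions region labels.
#' @param seed RNG seed.
#' @return data.frame: `region`, `animal`, `slice`, `tsi`, `csa`,
#'   `size_index` (= tsi), `mean_hu`, `density_mg_ml`; true parameters in
#'   attribute `truth`.
#' @export
simulate_phantom_observations <- function(n_per_region = 18,
                                          size_range = c(2, 9),
                                          B = c(60, 130, 230, 430),
                                          A = c(30, 30.5, 45, 60),
                                          noise_sd = 1,
                                          csa_scale = 4000,
                                          csa_log_noise = 0.15,
                                          regions = c("P1", "P2", "P3", "P4"),
                                          seed = NULL) {
  stopifnot(noise_sd >= 0, all(size_range > 0), size_range[1] < size_range[2])
  k <- length(regions)
  B <- rep_len(B, k); A <- rep_len(A, k)
  densities <- rep_len(c(0, 50, 100, 200), k)
  with_seed(seed, {
    tsi <- exp(stats::runif(n_per_region, log(size_range[1]),
                            log(size_range[2])))
    csa <- csa_scale * tsi * exp(stats::rnorm(n_per_region, 0, csa_log_noise))
    out <- do.call(rbind, lapply(seq_len(k), function(r) {
      data.frame(region = regions[r],
                 animal = sprintf("sim%02d", seq_len(n_per_region)),
                 slice = seq_len(n_per_region),
                 tsi = tsi, csa = csa, size_index = tsi,
                 mean_hu = B[r] - A[r] * log(tsi) +
                   stats::rnorm(n_per_region, 0, noise_sd),
                 density_mg_ml = densities[r])
    }))
    attr(out, "truth") <- list(B = B, A = A, noise_sd = noise_sd,
                               size_range = size_range,
                               csa_scale = csa_scale,
                               csa_log_noise = csa_log_noise)
    out
  })
}

# Round to the nearest half point and clip to the 0-4 scale: scores are
# means of two integer reads.
round_score <- function(x) pmin(4, pmax(0, round(x * 2) / 2))

#' Simulate a study cohort of kidneys
#'
#' Emulates the study design: exposure groups of animals (defaults: 10
#' total-body irradiated, 10 chest-only, 2 unirradiated controls), two
#' kidneys per animal, an animal-level size index, and per-kidney fibrosis
#' scores. The measurement model composes a fibrosis-driven true HU with the
#' size-driven beam-hardening bias:
#'
#' \deqn{measured = base + effect \cdot score - A \ln(size / size_0) + N(0, \sigma)}
#'
#' The bias is injected at the measurement level exactly as the calibration
#' models it, so the configured truth is recoverable by the correction. The
#' reference `size0` is the realized cohort mean size (the same normalization
#' convention the corrector uses). Defaults echo the observed anchors: a base
#' corrected cortical HU of 46 with ~5.5 HU per score unit spans roughly
#' 45-65 HU over the 0-3.5 score range; group mean scores of 2.0 (total
#' body), 0.5 (chest only) and ~0.1 (control); TSI between 2 and 9.
#'
#' Histological blue-area fractions are generated as an affine function of
#' the score plus noise, giving a correlated second ground-truth method.
#'
#' When `prevalence` is supplied, scores are instead drawn by flipping a
#' fibrosis coin per kidney at that rate (scores >= 1 for positives, < 1 for
#' negatives), which pins the expected fibrosis prevalence directly.
#'
#' @param n_per_group named integer vector of animals per exposure group.
#' @param score_mean named per-group mean of the latent score.
#' @param score_sd SD of the animal-level latent score.
#' @param kidney_score_sd SD of the per-kidney deviation from the animal
#'   latent.
#' @param base_hu true cortical HU at score 0.
#' @param effect_hu_per_score HU added per fibrosis score unit.
#' @param animal_hu_sd SD of animal-level biological HU variation unrelated
#'   to fibrosis (perfusion, hydration, composition); keeps simulated
#'   discrimination realistic rather than perfect.
#' @param A beam-hardening coefficient generating the size bias. The default
#'   (30) makes the bias large enough to mask the fibrosis signal in
#'   uncorrected CT numbers, the situation the correction exists for.
#' @param size_range animal TSI range; sizes are drawn log-uniformly over it,
#'   reflecting a cohort of deliberately varied subject sizes.
#' @param noise_sd per-kidney HU measurement noise.
#' @param blue_base,blue_per_score,blue_sd blue-fraction model parameters.
#' @param prevalence optional direct fibrosis prevalence.
#' @param seed RNG seed.
#' @return cohort data.frame (see [read_cohort_table()]) with extra column
#'   `true_hu`; generating parameters (including the realized `size0`) in
#'   attribute `truth`.
#' @export
simulate_cohort <- function(n_per_group = c(total_body = 10, chest_only = 10,
                                            control = 2),
                            score_mean = c(total_body = 2.0, chest_only = 0.5,
                                           control = 0.1),
                            score_sd = 0.9, kidney_score_sd = 0.25,
                            base_hu = 46, effect_hu_per_score = 5.5,
                            animal_hu_sd = 3, A = 30,
                            size_range = c(2, 9),
                            noise_sd = 2,
                            blue_base = 0.02, blue_per_score = 0.06,
                            blue_sd = 0.01,
                            prevalence = NULL, seed = NULL) {
  stopifnot(noise_sd >= 0, score_sd >= 0, kidney_score_sd >= 0, blue_sd >= 0)
  groups <- names(n_per_group)
  if (is.null(groups)) stop("'n_per_group' must be named", call. = FALSE)
  with_seed(seed, {
    rows <- list()
    aid <- 0L
    for (g in groups) {
      for (i in seq_len(n_per_group[[g]])) {
        aid <- aid + 1L
        animal <- sprintf("A%03d", aid)
        size <- exp(stats::runif(1, log(size_range[1]), log(size_range[2])))
        if (is.null(prevalence)) {
          latent <- stats::rnorm(1, score_mean[[g]], score_sd)
          scores <- round_score(latent +
                                  stats::rnorm(2, 0, kidney_score_sd))
        } else {
          fib <- stats::runif(2) < prevalence
          scores <- ifelse(fib,
                           sample(seq(1, 4, by = 0.5), 2, replace = TRUE),
                           sample(c(0, 0.5), 2, replace = TRUE))
        }
        rows[[aid]] <- data.frame(
          animal = animal, side = c("left", "right"), group = g,
          size_index = size, fibrosis_score = scores,
          animal_hu_shift = stats::rnorm(1, 0, animal_hu_sd))
      }
    }
    out <- do.call(rbind, rows)
    size0 <- mean(tapply(out$size_index, out$animal, unique))
    out$true_hu <- base_hu + effect_hu_per_score * out$fibrosis_score +
      out$animal_hu_shift
    out$animal_hu_shift <- NULL
    out$measured_hu <- out$true_hu - A * log(out$size_index / size0) +
      stats::rnorm(nrow(out), 0, noise_sd)
    out$corrected_hu <- NA_real_
    out$blue_fraction <- pmin(1, pmax(0,
                                      blue_base + blue_per_score * out$fibrosis_score +
                                        stats::rnorm(nrow(out), 0, blue_sd)))
    out$bun <- NA_real_
    rownames(out) <- NULL
    attr(out, "truth") <- list(base_hu = base_hu,
                               effect_hu_per_score = effect_hu_per_score,
                               A = A, size0 = size0, noise_sd = noise_sd,
                               prevalence = prevalence,
                               score_mean = score_mean)
    out
  })
}

#' Render a synthetic axial CT slice with ROI masks
#'
#' Builds a 2-D HU raster emulating a scan: air everywhere, a body ellipse of
#' soft-tissue HU centred (by default) in the field of view, and optional
#' organ ellipses (e.g. kidneys, a phantom insert) of given HU inside the
#' body. Returns the raster plus matching ROI masks (`FOV`, `body`, one per
#' organ) so the size-index and ROI machinery can be validated against the
#' analytically known geometry.
#'
#' @param matrix_size raster dimension (square); default 256.
#' @param fov_diameter_mm reconstruction circle diameter; default 320.
#' @param body optional list `list(center = c(x, y) mm offsets from FOV
#'   centre, axes = c(a, b) semi-axes mm, hu = value)`; `NULL` renders an
#'   all-air slice.
#' @param organs list of lists like `body` with an extra `label`.
#' @param air_hu background HU; default -1024.
#' @param noise_sd optional Gaussian HU noise.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return list: `slice` (matrix), `spacing` (mm), `fov_diameter_mm`,
#'   `masks` (named list of logical matrices), `air_hu`.
#' @export
render_ct_slice <- function(matrix_size = 256, fov_diameter_mm = 320,
                            body = NULL, organs = list(), air_hu = -1024,
                            noise_sd = 0, seed = NULL) {
  spacing <- fov_diameter_mm / matrix_size
  dims <- c(matrix_size, matrix_size)
  centre <- (matrix_size - 1) * spacing / 2
  cx <- (seq_len(matrix_size) - 1L) * spacing - centre
  cy <- cx
  inside_ellipse <- function(e) {
    outer(cx, cy, function(x, y)
      ((x - e$center[1]) / e$axes[1])^2 + ((y - e$center[2]) / e$axes[2])^2 <= 1)
  }
  check_inside <- function(inner, outer_c, outer_ax, what) {
    reach <- abs(inner$center) + inner$axes
    if (any(reach > outer_ax - abs(outer_c)))
      stop(what, " extends outside its container", call. = FALSE)
  }
  slice <- matrix(air_hu, matrix_size, matrix_size)
  masks <- list(FOV = fov_mask(dims, rep(spacing, 2), fov_diameter_mm))
  if (!is.null(body)) {
    body$center <- body$center %||% c(0, 0)
    check_inside(body, c(0, 0), rep(fov_diameter_mm / 2, 2), "body ellipse")
    bm <- inside_ellipse(body)
    slice[bm] <- body$hu
    masks$body <- bm
    for (org in organs) {
      check_inside(org, body$center, body$axes, paste0("organ '", org$label, "'"))
      om <- inside_ellipse(org)
      slice[om] <- org$hu
      masks[[org$label]] <- om
    }
  } else if (length(organs)) {
    stop("organs require a body ellipse", call. = FALSE)
  }
  if (noise_sd > 0)
    slice <- with_seed(seed, slice + stats::rnorm(length(slice), 0, noise_sd))
  list(slice = slice, spacing = spacing, fov_diameter_mm = fov_diameter_mm,
       masks = masks, air_hu = air_hu)
}

#' Render a synthetic trichrome image with known blue fraction
#'
#' Produces an RGB image emulating a Masson-trichrome section: a pink tissue
#' texture with blue (collagen-like) blobs on a white background, with
#' per-pixel colour jitter inside each class. After laying down blob
#' geometry the class assignment is adjusted pixel-by-pixel so the realized
#' blue fraction equals `round(target_fraction * n_pixels) / n_pixels`
#' (within 1/n of the target, comfortably inside 0.005 at default size).
#' Deterministic under a fixed seed.
#'
#' @param target_fraction desired blue-area fraction in `[0, 1]`.
#' @param width,height image size in pixels.
#' @param tissue_fraction approximate fraction of the frame covered by
#'   tissue (pink + blue) before adjustment.
#' @param n_blobs number of blue blobs.
#' @param seed RNG seed.
#' @return `h x w x 3` array on 0-255 with attributes `realized_fraction`
#'   and `class_mask` (1 white, 2 pink, 3 blue).
#' @export
render_trichrome <- function(target_fraction, width = 200, height = 200,
                             tissue_fraction = 0.85, n_blobs = 8,
                             seed = NULL) {
  if (!is.finite(target_fraction) || target_fraction < 0 || target_fraction > 1)
    stop("'target_fraction' must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    n <- width * height
    xs <- matrix(rep(seq_len(width), each = height), height, width)
    ys <- matrix(rep(seq_len(height), width), height, width)
    # tissue region: big central ellipse
    tis <- ((xs - width / 2) / (width / 2 * sqrt(tissue_fraction)))^2 +
      ((ys - height / 2) / (height / 2 * sqrt(tissue_fraction)))^2 <= 1.3
    cls <- matrix(1L, height, width)  # 1 = white
    cls[tis] <- 2L                    # 2 = pink
    n_blue <- round(target_fraction * n)
    # seed blue blobs inside the tissue
    if (n_blue > 0 && any(tis)) {
      blue <- matrix(FALSE, height, width)
      r0 <- sqrt(n_blue / max(n_blobs, 1) / pi)
      for (b in seq_len(n_blobs)) {
        idx <- which(tis)
        c_i <- idx[sample.int(length(idx), 1)]
        cyx <- c((c_i - 1) %% height + 1, (c_i - 1) %/% height + 1)
        rr <- r0 * stats::runif(1, 0.6, 1.4)
        blue <- blue | (((xs - cyx[2])^2 + (ys - cyx[1])^2) <= rr^2 & tis)
      }
      cls[blue] <- 3L
    }
    # exact-count adjustment: promote/demote random tissue pixels
    delta <- n_blue - sum(cls == 3L)
    if (delta > 0) {
      cand <- which(cls == 2L)
      if (length(cand) < delta) cand <- which(cls != 3L)
      cls[cand[sample.int(length(cand), delta)]] <- 3L
    } else if (delta < 0) {
      cand <- which(cls == 3L)
      cls[cand[sample.int(length(cand), -delta)]] <- 2L
    }
    # class colours with jitter, kept inside/outside the default HSB windows
    img <- array(0, dim = c(height, width, 3))
    jit <- function(n, centre, amp) pmin(255, pmax(0, centre +
                                                     stats::runif(n, -amp, amp)))
    for (channel in 1:3) {
      v <- numeric(n)
      w <- cls == 1L
      v[w] <- jit(sum(w), 248, 5)
      p <- cls == 2L
      v[p] <- jit(sum(p), c(232, 128, 168)[channel], c(12, 18, 18)[channel])
      bl <- cls == 3L
      v[bl] <- jit(sum(bl), c(35, 65, 200)[channel], c(15, 18, 28)[channel])
      img[, , channel] <- matrix(v, height, width)
    }
    img <- round(img)
    structure(img, realized_fraction = sum(cls == 3L) / n, class_mask = cls)
  })
}
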