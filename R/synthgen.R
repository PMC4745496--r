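#' Build a synthetic sample specification
#'
#' Convenience constructor for [SampleSpec-class] with the generator's
#' default acquisition conditions: a 480 x 640 chamber frame, fruit
#' semi-axes around 150 x 170 pixels, mild salt-and-pepper noise
#' (probability 0.002) and optical blur (sigma 0.6 px).
#'
#' @param maturity ripeness in \[0, 1\].
#' @param disease `"none"` or one of [diseaseArchetypes()].
#' @param lesionFraction target lesion coverage of the fruit area; must
#'   be 0 for healthy fruit and positive for infected fruit. Default 0.1
#'   when infected.
#' @param fruitAxes ellipse semi-axes `c(row, col)` in pixels.
#' @param noiseImpulse per-pixel impulse probability.
#' @param noiseBlur Gaussian blur sigma (0 disables).
#' @param seed RNG seed; the whole render is a deterministic function of
#'   the spec.
#' @param canvas `c(height, width)`, default `c(480, 640)`.
#' @return a validated [SampleSpec-class].
#' @export
sampleSpec <- function(maturity = 0.5, disease = "none",
                       lesionFraction = if (disease == "none") 0 else 0.1,
                       fruitAxes = c(150, 170), noiseImpulse = 0.002,
                       noiseBlur = 0.6, seed = 0L,
                       canvas = c(480L, 640L)) {
  new("SampleSpec", maturity = as.numeric(maturity),
      disease = as.character(disease),
      lesionFraction = as.numeric(lesionFraction),
      fruitAxes = as.numeric(fruitAxes),
      noiseImpulse = as.numeric(noiseImpulse),
      noiseBlur = as.numeric(noiseBlur), seed = as.integer(seed),
      canvas = as.integer(canvas))
}

# colour ramp endpoints of the maturity trajectory (RGB, 0-255)
rampGreen <- c(60, 140, 50)
rampRed <- c(180, 30, 25)

clamp255 <- function(v) pmin(pmax(v, 0), 255)

# separable Gaussian blur with edge replication (direct convolution; the
# kernels here are tiny, so this beats an FFT pass by a wide margin)
blurSep <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  wts <- stats::dnorm(-r:r, sd = sigma)
  wts <- wts / sum(wts)
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (t in -r:r)
    out <- out + wts[t + r + 1] * x[pmin(pmax(1:h + t, 1L), h), ,
                                    drop = FALSE]
  x2 <- out
  out <- matrix(0, h, w)
  for (t in -r:r)
    out <- out + wts[t + r + 1] * x2[, pmin(pmax(1:w + t, 1L), w),
                                     drop = FALSE]
  out
}

#' Render one synthetic tomato frame pair
#'
#' Produces the two frames the segmentation stage expects -- the empty
#' chamber and the same chamber with a fruit -- plus full ground truth.
#' The fruit is a shaded ellipsoid whose base colour interpolates the
#' green-to-red ripening trajectory with `maturity`; disease archetypes
#' render their characteristic morphology (dark concentric annuli,
#' irregular brown blotches, dark-centre spots with white halos,
#' low-saturation gray patches, or many tiny dark specks). Impulse noise
#' and Gaussian blur are then applied to both frames. Identical specs
#' give bit-identical output.
#'
#' @param spec a [SampleSpec-class] (see [sampleSpec()]).
#' @return list with `background` and `sample` (RGB arrays) and `truth`:
#'   `fruitMask`, `lesionMask`, `maturity`, `maturityLabel`,
#'   `healthLabel`, `diseaseLabel`, `lesionFraction` (realised), and
#'   `trueColorFractions` of the noiseless render.
#' @export
generateSample <- function(spec) {
  stopifnot(is(spec, "SampleSpec"))
  validObject(spec)
  withSeed(spec@seed, renderSample(spec))
}

renderSample <- function(spec) {
  h <- spec@canvas[1]; w <- spec@canvas[2]
  # dark chamber wall: fixed mild vertical illumination gradient
  bgLevel <- 16 + 6 * (seq_len(h) - 1) / max(h - 1, 1)
  bgPlane <- matrix(bgLevel, h, w)

  # fruit geometry: centred ellipse with small jitter
  cy <- h / 2 + stats::runif(1, -0.02, 0.02) * h
  cx <- w / 2 + stats::runif(1, -0.02, 0.02) * w
  ay <- min(spec@fruitAxes[1] * stats::runif(1, 0.95, 1.05), (h - 4) / 2)
  ax <- min(spec@fruitAxes[2] * stats::runif(1, 0.95, 1.05), (w - 4) / 2)
  rowScaled2 <- ((seq_len(h) - cy) / ay)^2
  colScaled2 <- ((seq_len(w) - cx) / ax)^2
  r2 <- outer(rowScaled2, colScaled2, "+")
  fruitMask <- r2 <= 1
  fruitIdx <- which(fruitMask)

  # base colour: linear green->red ramp plus a small per-sample cast,
  # spherical shading and shared-luminance surface mottle
  cast <- stats::runif(3, -8, 8)
  base <- clamp255((1 - spec@maturity) * rampGreen +
                   spec@maturity * rampRed + cast)
  shade <- 0.55 + 0.45 * sqrt(pmax(1 - r2[fruitIdx], 0))
  mottle <- stats::rnorm(length(fruitIdx), 0, 4)
  planes <- vector("list", 3L)
  for (ch in 1:3) {
    p <- bgPlane
    p[fruitIdx] <- clamp255(base[ch] * shade + mottle)
    planes[[ch]] <- p
  }

  lesionMask <- matrix(FALSE, h, w)
  if (spec@disease != "none") {
    les <- renderLesions(spec@disease, spec@lesionFraction, fruitMask,
                         cy, cx, ay, ax, h, w)
    lesionMask <- les$mask
    # apply accumulated paint; duplicate indices resolve in paint order
    for (ch in 1:3) {
      p <- planes[[ch]]
      p[les$idx] <- les$values[[ch]]
      planes[[ch]] <- p
    }
  }

  # fractions of the noiseless render, on the emitted 8-bit scale
  sums <- vapply(planes, function(p) sum(round(p[fruitIdx])), 0)
  trueCF <- stats::setNames(100 * sums / sum(sums), c("R", "G", "B"))

  bgPlanes <- list(bgPlane, bgPlane, bgPlane)
  if (spec@noiseBlur > 0) {
    blurredBg <- clamp255(blurSep(bgPlane, spec@noiseBlur))
    bgPlanes <- list(blurredBg, blurredBg, blurredBg)
    planes <- lapply(planes, function(p)
      clamp255(blurSep(p, spec@noiseBlur)))
  }
  if (spec@noiseImpulse > 0) {
    bgPlanes <- addImpulseNoise(bgPlanes, spec@noiseImpulse)
    planes <- addImpulseNoise(planes, spec@noiseImpulse)
  }
  background <- round(array(c(bgPlanes[[1]], bgPlanes[[2]],
                              bgPlanes[[3]]), dim = c(h, w, 3L)))
  sample <- round(array(c(planes[[1]], planes[[2]], planes[[3]]),
                        dim = c(h, w, 3L)))

  list(background = background, sample = sample,
       truth = list(
         fruitMask = fruitMask, lesionMask = lesionMask,
         maturity = spec@maturity,
         maturityLabel = maturityToLabel(spec@maturity),
         healthLabel = if (any(lesionMask)) "risky" else "healthy",
         diseaseLabel = if (any(lesionMask)) spec@disease else "none",
         lesionFraction = sum(lesionMask) / sum(fruitMask),
         trueColorFractions = trueCF))
}

# salt-and-pepper: each hit pixel goes to 0 or 255 on all channels
addImpulseNoise <- function(planes, prob) {
  n <- length(planes[[1]])
  hit <- which(stats::runif(n) < prob)
  if (!length(hit)) return(planes)
  val <- ifelse(stats::runif(length(hit)) < 0.5, 0, 255)
  lapply(planes, function(p) { p[hit] <- val; p })
}

# linear indices of a disk clipped to the fruit, via a local window only
diskIdx <- function(cy, cx, rad, fruitMask, h, w) {
  i0 <- max(1L, floor(cy - rad)); i1 <- min(h, ceiling(cy + rad))
  j0 <- max(1L, floor(cx - rad)); j1 <- min(w, ceiling(cx + rad))
  if (i0 > i1 || j0 > j1) return(integer(0))
  ii <- i0:i1; jj <- j0:j1
  inside <- outer((ii - cy)^2, (jj - cx)^2, "+") <= rad^2
  idx <- outer(ii, (jj - 1L) * h, "+")[inside]
  idx[fruitMask[idx]]
}

# place lesion elements until the union covers ~targetFraction of the
# fruit; each archetype has its own element shape and palette. Returns
# the union mask plus per-channel paint values registered to `idx`
# (applied in order, so later elements overwrite earlier ones).
renderLesions <- function(disease, targetFraction, fruitMask,
                          cy, cx, ay, ax, h, w) {
  fruitArea <- sum(fruitMask)
  target <- targetFraction * fruitArea
  mask <- matrix(FALSE, h, w)
  idxAcc <- list(); valAcc <- list(list(), list(), list())
  nAcc <- 0L
  paint <- function(idx, color, jitterSd = 0) {
    if (!length(idx)) return(invisible())
    nAcc <<- nAcc + 1L
    idxAcc[[nAcc]] <<- idx
    jit <- if (jitterSd > 0) stats::rnorm(length(idx), 0, jitterSd) else 0
    for (ch in 1:3)
      valAcc[[ch]][[nAcc]] <<- clamp255(color[ch] + jit)
    mask[idx] <<- TRUE
  }
  # sample a lesion centre well inside the fruit
  lesionCentre <- function(maxR = 0.75) {
    u <- sqrt(stats::runif(1)) * maxR
    th <- stats::runif(1, 0, 2 * pi)
    c(cy + u * ay * sin(th), cx + u * ax * cos(th))
  }

  if (disease == "early_blight") {
    # one or two large sunken lesions with concentric dark rings
    nL <- sample(1:2, 1)
    radius <- sqrt(target / (pi * nL))
    guard <- 0L
    while (sum(mask) < 0.95 * target && (guard <- guard + 1L) <= 12L) {
      ctr <- lesionCentre(0.55)
      idx <- diskIdx(ctr[1], ctr[2], radius, fruitMask, h, w)
      rows <- ((idx - 1L) %% h) + 1L
      cols <- ((idx - 1L) %/% h) + 1L
      d <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
      ringW <- max(3, radius / 5)
      dark <- c(55, 38, 24); darker <- c(24, 16, 10)
      ringSel <- (floor(d / ringW) %% 2) == 0
      jit <- stats::rnorm(length(idx), 0, 5)
      nAcc <- nAcc + 1L
      idxAcc[[nAcc]] <- idx
      for (ch in 1:3)
        valAcc[[ch]][[nAcc]] <-
          clamp255(ifelse(ringSel, dark[ch], darker[ch]) + jit)
      mask[idx] <- TRUE
    }
  } else if (disease == "late_blight") {
    # irregular brown blotch: union of overlapping random disks
    ctr <- lesionCentre(0.5)
    guard <- 0L
    while (sum(mask) < 0.95 * target && (guard <- guard + 1L) <= 60L) {
      off <- stats::rnorm(2, 0, sqrt(target) / 3)
      rad <- sqrt(0.18 * max(target - sum(mask), 25) / pi) *
        stats::runif(1, 0.8, 1.6)
      paint(diskIdx(ctr[1] + off[1], ctr[2] + off[2], rad, fruitMask,
                    h, w),
            c(55, 35, 18), jitterSd = 10)
    }
  } else if (disease == "bacterial_canker") {
    # "bird's eye": small dark centres ringed by white halos
    guard <- 0L
    while (sum(mask) < 0.95 * target && (guard <- guard + 1L) <= 400L) {
      ctr <- lesionCentre(0.8)
      rad <- stats::runif(1, 3, 6)
      halo <- diskIdx(ctr[1], ctr[2], rad + 2.5, fruitMask, h, w)
      core <- diskIdx(ctr[1], ctr[2], rad, fruitMask, h, w)
      paint(setdiff(halo, core), c(232, 226, 208), jitterSd = 6)
      paint(core, c(74, 46, 28), jitterSd = 6)
    }
  } else if (disease == "gray_mold") {
    # low-saturation fuzzy gray patches
    guard <- 0L
    while (sum(mask) < 0.95 * target && (guard <- guard + 1L) <= 80L) {
      ctr <- lesionCentre(0.6)
      patchTarget <- min(target - sum(mask), 0.35 * target)
      inner <- 0L
      while (sum(mask) < 0.95 * target && (inner <- inner + 1L) <= 25L) {
        off <- stats::rnorm(2, 0, sqrt(patchTarget) / 4)
        rad <- sqrt(0.3 * max(patchTarget, 25) / pi) *
          stats::runif(1, 0.7, 1.3)
        paint(diskIdx(ctr[1] + off[1], ctr[2] + off[2], rad, fruitMask,
                      h, w),
              c(152, 147, 140), jitterSd = 10)
      }
    }
  } else if (disease == "bacterial_speck") {
    # many tiny (<= 3 px across) dark raised dots
    dotArea <- 5  # ~ radius-1.2 disk
    nDots <- max(4L, ceiling(target / dotArea))
    for (i in seq_len(nDots)) {
      if (sum(mask) >= 0.95 * target) break
      ctr <- lesionCentre(0.85)
      paint(diskIdx(ctr[1], ctr[2], stats::runif(1, 0.8, 1.5), fruitMask,
                    h, w),
            c(30, 22, 14), jitterSd = 4)
    }
  }
  list(mask = mask, idx = unlist(idxAcc),
       values = lapply(valAcc, unlist))
}

#' Generate a labelled synthetic dataset
#'
#' Renders `nHealthy + nInfected` frame pairs with ground truth. Each
#' sample's RNG stream is derived from `(seed, index)`, so a dataset is
#' reproducible and stable under partial regeneration. Maturities are
#' drawn from `stageMix`, infected samples cycle through `diseaseMix`,
#' and lesion coverage is drawn uniformly from `lesionRange`
#' (`bacterial_speck` uses a quarter of that coverage -- specks are tiny).
#'
#' @param nHealthy,nInfected sample counts (>= 0).
#' @param stageMix probabilities of the `u`/`m`/`r` maturity thirds,
#'   default balanced.
#' @param diseaseMix archetypes to cycle over for infected samples;
#'   default all five.
#' @param lesionRange lesion-fraction range, default `c(0.06, 0.18)`.
#' @param seed master RNG seed.
#' @param outDir if non-NULL, background/sample PNG pairs and a
#'   `manifest.csv` are written there.
#' @param canvas,fruitAxes,noiseImpulse,noiseBlur forwarded to
#'   [sampleSpec()].
#' @return invisibly, a list with `manifest` (data.frame) and `samples`
#'   (the rendered pairs and truths, in manifest order).
#' @export
generateDataset <- function(nHealthy, nInfected,
                            stageMix = c(1, 1, 1) / 3,
                            diseaseMix = diseaseArchetypes(),
                            lesionRange = c(0.06, 0.18),
                            seed = 0L, outDir = NULL,
                            canvas = c(480L, 640L),
                            fruitAxes = c(150, 170),
                            noiseImpulse = 0.002, noiseBlur = 0.6) {
  nHealthy <- as.integer(nHealthy); nInfected <- as.integer(nInfected)
  if (nHealthy < 0L || nInfected < 0L) stopParameter("counts must be >= 0")
  if (length(stageMix) != 3L || any(stageMix < 0) || sum(stageMix) <= 0)
    stopParameter("stageMix must be 3 non-negative weights")
  stageMix <- stageMix / sum(stageMix)
  if (!all(diseaseMix %in% diseaseArchetypes()))
    stopParameter("unknown archetype in diseaseMix")
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) {
      ok <- tryCatch(dir.create(outDir, recursive = TRUE),
                     warning = function(w) FALSE)
      if (!isTRUE(ok)) stopIO("cannot create output directory: ", outDir)
    }
  }
  n <- nHealthy + nInfected
  health <- rep(c("healthy", "risky"), c(nHealthy, nInfected))
  rowsOut <- vector("list", n)
  samples <- vector("list", n)
  infIdx <- 0L
  for (i in seq_len(n)) {
    sampleSeed <- (as.numeric(seed) * 1000 + 7 * i) %% 2147483647
    drawn <- withSeed(sampleSeed + 1, {
      third <- sample.int(3L, 1L, prob = stageMix)
      list(maturity = stats::runif(1, (third - 1) / 3, third / 3),
           lesion = stats::runif(1, lesionRange[1], lesionRange[2]))
    })
    if (health[i] == "risky") {
      infIdx <- infIdx + 1L
      disease <- diseaseMix[((infIdx - 1L) %% length(diseaseMix)) + 1L]
      lesionFraction <- if (disease == "bacterial_speck")
        drawn$lesion / 4 else drawn$lesion
    } else {
      disease <- "none"; lesionFraction <- 0
    }
    spec <- sampleSpec(maturity = drawn$maturity, disease = disease,
                       lesionFraction = lesionFraction,
                       fruitAxes = fruitAxes, noiseImpulse = noiseImpulse,
                       noiseBlur = noiseBlur, seed = sampleSeed,
                       canvas = canvas)
    rendered <- generateSample(spec)
    samples[[i]] <- rendered
    id <- sprintf("S%03d", i)
    bgPath <- samplePath <- NA_character_
    if (!is.null(outDir)) {
      bgPath <- file.path(outDir, paste0(id, "_background.png"))
      samplePath <- file.path(outDir, paste0(id, "_sample.png"))
      writeImage(rendered$background, bgPath)
      writeImage(rendered$sample, samplePath)
    }
    tr <- rendered$truth
    rowsOut[[i]] <- data.frame(
      sample_id = id, background = bgPath, sample = samplePath,
      maturity = spec@maturity, maturity_label = tr$maturityLabel,
      health_label = tr$healthLabel, disease_label = tr$diseaseLabel,
      lesion_fraction = tr$lesionFraction,
      true_R = tr$trueColorFractions[["R"]],
      true_G = tr$trueColorFractions[["G"]],
      true_B = tr$trueColorFractions[["B"]],
      seed = sampleSeed, stringsAsFactors = FALSE)
  }
  manifest <- if (n > 0) do.call(rbind, rowsOut) else
    data.frame(sample_id = character(0), background = character(0),
               sample = character(0), maturity = numeric(0),
               maturity_label = character(0), health_label = character(0),
               disease_label = character(0), lesion_fraction = numeric(0),
               true_R = numeric(0), true_G = numeric(0),
               true_B = numeric(0), seed = numeric(0))
  if (!is.null(outDir))
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
  invisible(list(manifest = manifest, samples = samples))
}

#' Read and write sample specifications as YAML
#'
#' A [SampleSpec-class] round-trips through a small YAML document, which
#' is the convenient on-disk form for scripted acquisition campaigns.
#'
#' @param spec a [SampleSpec-class].
#' @param path YAML file path.
#' @return `readSampleSpec()` returns the validated [SampleSpec-class].
#' @export
writeSampleSpec <- function(spec, path) {
  stopifnot(is(spec, "SampleSpec"))
  yaml::write_yaml(list(
    maturity = spec@maturity, disease = spec@disease,
    lesionFraction = spec@lesionFraction,
    fruitAxes = as.numeric(spec@fruitAxes),
    noiseImpulse = spec@noiseImpulse, noiseBlur = spec@noiseBlur,
    seed = spec@seed, canvas = as.integer(spec@canvas)), path)
  invisible(path)
}

#' @rdname writeSampleSpec
#' @export
readSampleSpec <- function(path) {
  if (!file.exists(path)) stopIO("no such spec file: ", path)
  do.call(sampleSpec, yaml::read_yaml(path))
}
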