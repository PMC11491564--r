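#' @include selection.R
NULL

# Run expr with a private RNG stream seeded by `seed`, restoring the
# caller's stream afterwards. All generator randomness goes through this.
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Default dipole wave components
#'
#' A normal-morphology beat as Gaussian bumps in beat phase (R peak at
#' phase 0): P, Q, R, S and T deflections. Each wave has its own frontal
#' axis (P around 50 degrees, QRS around 60-70, T around 40), so the X
#' and Y axis signals are linearly independent, and a distinct Z profile,
#' so the noise-free dipole spans rank 3. The spatial QRS peak is 2.2 mV
#' along its axis, in the range reported for healthy adult
#' vectorcardiograms.
#'
#' @return named list of data.frames (\code{x}, \code{y}, \code{z}) with
#'   columns \code{center} (rad), \code{width} (rad), \code{amplitude}
#'   (mV).
#' @export
defaultWaveComponents <- function() {
  waves <- data.frame(
    wave   = c("P", "Q", "R", "S", "T"),
    center = c(-1.05, -0.12, 0.00, 0.12, 1.55),
    width  = c(0.25, 0.08, 0.09, 0.08, 0.35),
    amp    = c(0.28, -0.20, 2.20, -0.50, 0.70),  # along the wave's own axis
    axisDeg = c(50, 65, 60, 70, 40),             # frontal-plane wave axis
    zAmp   = c(0.06, 0.04, -0.70, 0.16, 0.20)
  )
  th <- waves$axisDeg * pi / 180
  mk <- function(a) data.frame(center = waves$center, width = waves$width,
                               amplitude = a)
  list(x = mk(waves$amp * cos(th)),
       y = mk(waves$amp * sin(th)),
       z = mk(waves$zAmp))
}

#' Construct dipole generator parameters
#'
#' Defaults emulate a clean resting 12-lead recording: 10 s at 500 Hz,
#' 70 bpm with 5\% RR jitter, beat-to-beat respiratory modulation (8
#' degrees of frontal axis wobble and 15\% amplitude modulation per
#' beat), a small constant resting dipole offset that keeps every lead's
#' isoelectric baseline away from 0, 20 uV additive white noise per lead,
#' and a 4-degree per-record electrode-angle jitter.
#'
#' @param rateHz sampling rate (Hz); default 500.
#' @param durationS duration (s); default 10.
#' @param heartRateBpm mean heart rate; default 70.
#' @param rrJitterFrac RR-interval jitter fraction; default 0.05.
#' @param waveComponents per-axis Gaussian bump table (see
#'   \code{\link{defaultWaveComponents}}).
#' @param beatRotSd per-beat frontal-plane axis wobble SD (degrees);
#'   default 8.
#' @param beatScaleSd per-beat log-normal amplitude modulation SD;
#'   default 0.15.
#' @param restOffsetMv constant resting dipole offset, one value per axis
#'   (mV); default \code{c(0.2, 0.2, 0.2)}.
#' @param noiseSdMv additive white noise SD per lead (mV); default 0.02.
#' @param electrodeJitterDeg SD of the per-record, per-lead angular
#'   perturbation (degrees), constant within a record; default 4.
#' @param seed integer RNG seed.
#' @return A \linkS4class{DipoleParams}.
#' @export
dipoleParams <- function(rateHz = 500, durationS = 10, heartRateBpm = 70,
                         rrJitterFrac = 0.05,
                         waveComponents = defaultWaveComponents(),
                         beatRotSd = 8, beatScaleSd = 0.15,
                         restOffsetMv = c(0.2, 0.2, 0.2),
                         noiseSdMv = 0.02, electrodeJitterDeg = 4,
                         seed = 1L) {
  obj <- try(new("DipoleParams", rateHz = as.numeric(rateHz),
                 durationS = as.numeric(durationS),
                 heartRateBpm = as.numeric(heartRateBpm),
                 rrJitterFrac = as.numeric(rrJitterFrac),
                 waveComponents = waveComponents,
                 beatRotSd = as.numeric(beatRotSd),
                 beatScaleSd = as.numeric(beatScaleSd),
                 restOffsetMv = as.numeric(restOffsetMv),
                 noiseSdMv = as.numeric(noiseSdMv),
                 electrodeJitterDeg = as.numeric(electrodeJitterDeg),
                 seed = as.integer(seed)), silent = TRUE)
  if (inherits(obj, "try-error"))
    .stopContract(sub(".*: ", "", attr(obj, "condition")$message))
  obj
}

# dipole axis signals without seeding (caller manages the RNG stream)
.vcgCore <- function(params) {
  n <- round(params@rateHz * params@durationS)
  t <- (seq_len(n) - 1) / params@rateHz
  baseRR <- 60 / params@heartRateBpm
  out <- matrix(0, n, 3, dimnames = list(NULL, c("X", "Y", "Z")))
  axes <- c("x", "y", "z")
  tk <- -baseRR  # one beat of margin before the record
  while (tk < params@durationS + baseRR) {
    rr <- baseRR * (1 + params@rrJitterFrac * stats::rnorm(1))
    rr <- max(rr, 0.2 * baseRR)
    br <- stats::rnorm(1, 0, params@beatRotSd) * pi / 180
    bs <- exp(stats::rnorm(1, 0, params@beatScaleSd))
    lo <- max(1L, ceiling((tk - rr / 2) * params@rateHz) + 1L)
    hi <- min(n, floor((tk + rr / 2) * params@rateHz) + 1L)
    if (lo <= hi) {
      phase <- 2 * pi * (t[lo:hi] - tk) / rr
      seg <- matrix(0, hi - lo + 1L, 3L)
      for (a in 1:3) {
        wc <- params@waveComponents[[axes[a]]]
        for (w in seq_len(nrow(wc)))
          seg[, a] <- seg[, a] + wc$amplitude[w] *
            exp(-(phase - wc$center[w])^2 / (2 * wc$width[w]^2))
      }
      # per-beat respiratory modulation: frontal axis wobble + amplitude
      seg[, 1:2] <- seg[, 1:2] %*%
        matrix(c(cos(br), sin(br), -sin(br), cos(br)), 2, 2)
      out[lo:hi, ] <- out[lo:hi, ] + seg * bs
    }
    tk <- tk + rr
  }
  sweep(out, 2, params@restOffsetMv, "+")
}

#' Simulate a dipole vectorcardiogram
#'
#' Generates the three orthogonal dipole axis signals X, Y, Z: each axis
#' a sum of Gaussian bumps in beat phase, beats placed at RR intervals of
#' 60/heart rate perturbed by the jitter fraction, each beat modulated in
#' amplitude and frontal axis (respiratory wobble), plus the constant
#' resting offset. Deterministic given the seed in \code{params}.
#'
#' @param params a \linkS4class{DipoleParams}.
#' @return A 3-channel \linkS4class{MultichannelRecord} (X, Y, Z).
#' @export
simulateVcg <- function(params) {
  stopifnot(is(params, "DipoleParams"))
  data <- .withSeed(params@seed, .vcgCore(params))
  MultichannelRecord(data, samplingRate = params@rateHz)
}

#' Project a dipole onto fixed lead directions
#'
#' A frontal-plane lead at angle theta is cos(theta) X + sin(theta) Y; a
#' transverse-plane lead is cos(theta) X + sin(theta) Z. Useful for
#' angle-ladder experiments relating inter-lead angle to shared
#' information.
#'
#' @param vcg a 3-channel record with channels X, Y, Z.
#' @param angles projection angles in degrees.
#' @param plane \code{"frontal"} or \code{"transverse"}.
#' @param names output channel names (default \code{"a<angle>"}).
#' @return A \linkS4class{MultichannelRecord} with one channel per angle.
#' @export
projectDipole <- function(vcg, angles, plane = c("frontal", "transverse"),
                          names = NULL) {
  stopifnot(is(vcg, "MultichannelRecord"))
  plane <- match.arg(plane)
  missing <- setdiff(c("X", "Y", "Z"), vcg@channelNames)
  if (length(missing))
    .stopContract(sprintf("vcg lacks channel(s): %s",
                          paste(missing, collapse = ", ")))
  X <- vcg@data[, match("X", vcg@channelNames)]
  sec <- if (plane == "frontal") vcg@data[, match("Y", vcg@channelNames)]
         else vcg@data[, match("Z", vcg@channelNames)]
  th <- angles * pi / 180
  out <- vapply(seq_along(th),
                function(k) cos(th[k]) * X + sin(th[k]) * sec,
                numeric(nrow(vcg@data)))
  if (is.null(names)) names <- paste0("a", angles)
  MultichannelRecord(out, channelNames = names,
                     samplingRate = vcg@samplingRate)
}

#' Simulate a standard 12-lead ECG record
#'
#' Projects a simulated dipole onto the 12 standard lead directions: limb
#' leads from the frontal plane (X, Y), precordial leads from the
#' transverse plane (X, Z), at the geometry table's angles. Each lead's
#' angle is perturbed by one seeded draw per record (electrode-placement
#' jitter, constant within the record), and per-lead additive white
#' noise is applied. With zero jitter and zero noise the Einthoven and
#' Goldberger identities hold exactly and the 12-lead covariance has
#' rank at most 3 (the dipole is three-dimensional).
#'
#' @param params a \linkS4class{DipoleParams}.
#' @param label optional class label to attach.
#' @param geometry lead geometry table (default
#'   \code{\link{leadGeometry}()}).
#' @return A 12-channel \linkS4class{MultichannelRecord}.
#' @export
simulate12Lead <- function(params, label = NA_character_,
                           geometry = leadGeometry()) {
  stopifnot(is(params, "DipoleParams"))
  .withSeed(params@seed, {
    vcg <- .vcgCore(params)
    n <- nrow(vcg)
    jit <- if (params@electrodeJitterDeg > 0)
      stats::rnorm(nrow(geometry), 0, params@electrodeJitterDeg)
    else rep(0, nrow(geometry))
    out <- matrix(0, n, nrow(geometry),
                  dimnames = list(NULL, geometry$lead))
    for (k in seq_len(nrow(geometry))) {
      th <- (geometry$angle[k] + jit[k]) * pi / 180
      sec <- if (geometry$plane[k] == "frontal") vcg[, "Y"] else vcg[, "Z"]
      out[, k] <- cos(th) * vcg[, "X"] + sin(th) * sec
    }
    if (params@noiseSdMv > 0)
      out <- out + matrix(stats::rnorm(length(out), 0, params@noiseSdMv),
                          nrow(out))
    MultichannelRecord(out, samplingRate = params@rateHz, label = label)
  })
}

# per-class morphology perturbations: frontal axis rotation (deg), global
# amplitude scale, global width scale. These exist to give the five labels
# distinguishable, reproducible morphologies for plumbing and
# class-weighting tests; they are not clinically validated waveforms.
.CLASS_PERTURB <- list(
  NORM = c(rot = 0,   amp = 1.00, width = 1.0),
  MI   = c(rot = -20, amp = 0.75, width = 1.0),
  STTC = c(rot = 10,  amp = 0.90, width = 1.15),
  CD   = c(rot = 0,   amp = 1.00, width = 1.40),
  HYP  = c(rot = 5,   amp = 1.40, width = 1.0)
)

# rotate the frontal wave axes and scale/widen all components
.perturbWaves <- function(params, rotDeg, ampScale, widthScale = 1) {
  wc <- params@waveComponents
  th <- rotDeg * pi / 180
  x <- wc$x$amplitude; y <- wc$y$amplitude
  wc$x$amplitude <- (cos(th) * x - sin(th) * y) * ampScale
  wc$y$amplitude <- (sin(th) * x + cos(th) * y) * ampScale
  wc$z$amplitude <- wc$z$amplitude * ampScale
  for (ax in c("x", "y", "z")) wc[[ax]]$width <- wc[[ax]]$width * widthScale
  dipoleParams(rateHz = params@rateHz, durationS = params@durationS,
               heartRateBpm = params@heartRateBpm,
               rrJitterFrac = params@rrJitterFrac, waveComponents = wc,
               beatRotSd = params@beatRotSd,
               beatScaleSd = params@beatScaleSd,
               restOffsetMv = params@restOffsetMv,
               noiseSdMv = params@noiseSdMv,
               electrodeJitterDeg = params@electrodeJitterDeg,
               seed = params@seed)
}

#' Simulate a labeled corpus of 12-lead records
#'
#' Draws class labels from the given mixture and simulates one record per
#' draw. Each record receives inter-subject variation — a seeded frontal
#' electrical-axis rotation (SD \code{subjectRotSd} degrees) and a
#' log-normal amplitude scale (SD \code{subjectScaleSd}) — on top of a
#' fixed per-class morphology perturbation (axis rotation, amplitude
#' scaling, wave widening). Fully reproducible from the base seed: record
#' i uses seed \code{seed + i}.
#'
#' @param nRecords number of records (>= 1).
#' @param classMix named fractions over NORM, MI, STTC, CD, HYP summing
#'   to 1 (default all NORM).
#' @param params base \linkS4class{DipoleParams}.
#' @param subjectRotSd SD of the per-record electrical-axis rotation
#'   (degrees); default 8, a homogeneous healthy population.
#' @param subjectScaleSd SD of the per-record log-normal amplitude scale;
#'   default 0.2.
#' @return A \linkS4class{RecordCollection} with labels set.
#' @export
simulateCorpus <- function(nRecords, classMix = c(NORM = 1),
                           params = dipoleParams(),
                           subjectRotSd = 8, subjectScaleSd = 0.2) {
  if (nRecords < 1) .stopContract("nRecords must be >= 1 (empty collection)")
  if (is.null(names(classMix)) ||
      !all(names(classMix) %in% .CLASS_LABELS))
    .stopContract(sprintf("classMix names must be among %s",
                          paste(.CLASS_LABELS, collapse = ", ")))
  if (abs(sum(classMix) - 1) > 1e-9)
    .stopContract("classMix fractions must sum to 1")
  draws <- .withSeed(params@seed, list(
    labels = sample(names(classMix), nRecords, replace = TRUE,
                    prob = classMix),
    rots = stats::rnorm(nRecords, 0, subjectRotSd),
    scales = exp(stats::rnorm(nRecords, 0, subjectScaleSd))))
  recs <- lapply(seq_len(nRecords), function(i) {
    cls <- .CLASS_PERTURB[[draws$labels[i]]]
    p <- .perturbWaves(params, rotDeg = cls[["rot"]] + draws$rots[i],
                       ampScale = cls[["amp"]] * draws$scales[i],
                       widthScale = cls[["width"]])
    p@seed <- as.integer((params@seed + i) %% .Machine$integer.max)
    simulate12Lead(p, label = draws$labels[i])
  })
  RecordCollection(recs)
}
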