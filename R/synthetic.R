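#' Action class vocabulary of the seated-behavior protocol
#'
#' Nine classes: six typical actions (idle, standing up, clapping, raising
#' one hand, pointing, turning the upper body) and three stereotypical
#' behaviors common in autism spectrum disorder (hand waving/flapping,
#' covering the ears, body rocking).
#'
#' @return character vector of the 9 class labels.
#' @export
actionClasses <- function() {
  c("IDLE", "STANDING", "CLAP", "HAND_WAVE", "HAND_RAISE", "POINTING",
    "COVER_EARS", "TURN", "ROCKING")
}

#' Skeleton bone list
#'
#' The 14 edges of the 15-joint skeleton tree, as pairs of canonical joint
#' indices. Useful for checking rigid-body properties of generated motion:
#' in a noiseless generated sequence every bone keeps a constant length.
#'
#' @return integer matrix with 14 rows and columns \code{from}, \code{to}.
#' @export
skeletonEdges <- function() {
  m <- rbind(c(1, 2), c(2, 3), c(2, 4), c(2, 7), c(4, 5), c(5, 6),
             c(7, 8), c(8, 9), c(3, 10), c(3, 13), c(10, 11), c(11, 12),
             c(13, 14), c(14, 15))
  storage.mode(m) <- "integer"
  colnames(m) <- c("from", "to")
  m
}

# Seated child-sized base posture, meters, camera frame: x lateral (subject
# left = +x as seen by the camera), y up, z depth (camera at z = 0, subject
# about 2 m away). Rows in canonical joint order.
.basePosture <- function() {
  matrix(c(
     0.00,  0.62, 2.00,   # head
     0.00,  0.50, 2.00,   # neck
     0.00,  0.32, 2.02,   # torso
     0.18,  0.48, 2.00,   # left shoulder
     0.23,  0.26, 1.98,   # left elbow
     0.25,  0.08, 1.90,   # left wrist
    -0.18,  0.48, 2.00,   # right shoulder
    -0.23,  0.26, 1.98,   # right elbow
    -0.25,  0.08, 1.90,   # right wrist
     0.12,  0.00, 2.00,   # left hip
     0.16, -0.02, 1.62,   # left knee
     0.17, -0.42, 1.66,   # left ankle
    -0.12,  0.00, 2.00,   # right hip
    -0.16, -0.02, 1.62,   # right knee
    -0.17, -0.42, 1.66),  # right ankle
    nrow = 15, ncol = 3, byrow = TRUE,
    dimnames = list(jointNames(), c("x", "y", "z")))
}

#' Draw the kinematic parameters of one simulated subject
#'
#' Inter-child variability is emulated with four documented draws: a global
#' limb-length scale in \code{[0.7, 1.1]} (child-sized bodies), small
#' per-joint posture offsets (normal, sd 8 mm), and motion amplitude and
#' frequency multipliers around 1. The draw is deterministic given
#' \code{(subjectId, seed)}; the subject-level stream is derived from the
#' master seed as \code{(seed + 9973 * subjectId) mod (2^31 - 1)}.
#'
#' @param subjectId positive integer id.
#' @param seed master seed.
#' @param sigma per-coordinate Gaussian noise level in meters applied to
#'   this subject's recordings (default 0.01, at most 0.02).
#' @return a list of class \code{SubjectParams} with elements
#'   \code{subjectId}, \code{scale}, \code{postureOffset} (15 x 3),
#'   \code{ampMult}, \code{freqMult}, \code{sigma}.
#' @export
sampleSubject <- function(subjectId, seed, sigma = 0.01) {
  stopifnot(subjectId >= 1, sigma >= 0, sigma <= 0.02)
  sseed <- as.integer((seed + 9973 * subjectId) %% 2147483647)
  p <- withr::with_seed(sseed, {
    list(subjectId = as.integer(subjectId),
         scale = stats::runif(1, 0.7, 1.1),
         postureOffset = matrix(stats::rnorm(45, sd = 0.008), 15, 3),
         ampMult = stats::runif(1, 0.75, 1.25),
         freqMult = stats::runif(1, 0.8, 1.2),
         sigma = sigma)
  })
  class(p) <- "SubjectParams"
  p
}

# Subject posture: base scaled about the hip center, plus fixed offsets.
.subjectPosture <- function(subject) {
  base <- .basePosture()
  hip <- colMeans(base[c(10, 13), ])
  base <- sweep(sweep(base, 2, hip) * subject$scale, 2, hip, "+")
  base + subject$postureOffset
}

.normalize <- function(v) v / sqrt(sum(v^2))

# Blend two unit directions and renormalize (keeps segment lengths fixed).
.blendDir <- function(d0, d1, u) {
  v <- (1 - u) * d0 + u * d1
  .normalize(v)
}

# Rodrigues rotation of point rows `pts` about the axis through `pt` with
# unit direction `ax` by angle `theta`.
.rotateAbout <- function(pts, pt, ax, theta) {
  v <- sweep(pts, 2, pt)
  cx <- cbind(ax[2] * v[, 3] - ax[3] * v[, 2],
              ax[3] * v[, 1] - ax[1] * v[, 3],
              ax[1] * v[, 2] - ax[2] * v[, 1])
  dotp <- drop(v %*% ax)
  out <- v * cos(theta) + cx * sin(theta) +
    outer(dotp * (1 - cos(theta)), ax)
  sweep(out, 2, pt, "+")
}

.smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

# Place one arm from per-frame unit directions. `d1`, `d2`: [N x 3] unit
# rows (shoulder -> elbow, elbow -> wrist).
.setArm <- function(coords, posture, side, d1, d2) {
  j <- if (side == "left") 4:6 else 7:9
  sh <- posture[j[1], ]
  L1 <- sqrt(sum((posture[j[2], ] - sh)^2))
  L2 <- sqrt(sum((posture[j[3], ] - posture[j[2], ])^2))
  elbow <- sweep(d1 * L1, 2, sh, "+")
  wrist <- elbow + d2 * L2
  coords[j[2], , ] <- t(elbow)
  coords[j[3], , ] <- t(wrist)
  coords
}

.armDirs <- function(posture, side) {
  j <- if (side == "left") 4:6 else 7:9
  list(d1 = .normalize(posture[j[2], ] - posture[j[1], ]),
       d2 = .normalize(posture[j[3], ] - posture[j[2], ]))
}

#' Generate one labeled action recording
#'
#' Animates a seated base skeleton with a class-specific parametric
#' trajectory built from rigid-limb kinematics: oscillations are rotations
#' or renormalized direction blends about anchor joints, so all bone lengths
#' stay constant within a noiseless sequence. The trajectories are
#' hand-designed sinusoids and ramps -- the goal is the statistical
#' structure of the behaviors (periodic limb motion, held postures,
#' whole-body rotation), not photorealism:
#' \itemize{
#'   \item \code{HAND_WAVE}: right forearm raised and oscillating about the
#'     shoulder at a nominal 4 Hz (hand-flapping).
#'   \item \code{ROCKING}: periodic ~1 Hz pitch of head/neck/spine and arms
#'     about the line through the hips.
#'   \item \code{COVER_EARS}: both wrists ramp to head height beside the
#'     head and hold.
#'   \item \code{CLAP}: anti-phase convergence of the wrists at the chest at
#'     ~2 Hz.
#'   \item \code{HAND_RAISE}: right arm raised above the head and held.
#'   \item \code{POINTING}: right arm extended toward the camera and held.
#'   \item \code{TURN}: ~0.4 Hz yaw oscillation of the upper body about the
#'     spine.
#'   \item \code{STANDING}: seated-to-upright transition (hip rise and
#'     knee extension).
#'   \item \code{IDLE}: base posture with a tiny postural sway.
#' }
#' The viewpoint applies a yaw of 0 / -90 / +90 degrees (front/left/right
#' camera placement) about the vertical axis through the hip center before
#' per-coordinate Gaussian noise (sd \code{subject$sigma}) is added.
#'
#' @param cls one of [actionClasses()].
#' @param subject a \code{SubjectParams} list from [sampleSubject()].
#' @param viewpoint \code{"front"}, \code{"left"} or \code{"right"}.
#' @param nFrames number of frames (>= 32; default 64, about two seconds at
#'   a nominal 30 fps).
#' @param seed seed for the observation noise.
#' @return a [SkeletonSequence-class] with metadata filled in.
#' @export
generateAction <- function(cls, subject, viewpoint = "front",
                           nFrames = 64L, seed = 1L) {
  cls <- toupper(cls)
  if (!cls %in% actionClasses())
    stop(sprintf("unknown action class '%s'; classes: %s", cls,
                 paste(actionClasses(), collapse = ", ")))
  if (!viewpoint %in% c("front", "left", "right"))
    stop("viewpoint must be 'front', 'left' or 'right'")
  if (nFrames < 32L) stop("nFrames must be >= 32")

  posture <- .subjectPosture(subject)
  n <- as.integer(nFrames)
  tt <- seq_len(n) - 1L
  dt <- 1 / 30                     # nominal sensor frame rate
  amp <- subject$ampMult
  phase <- function(f) 2 * pi * f * subject$freqMult * tt * dt

  coords <- array(rep(t(posture), n), dim = c(3L, 15L, n))
  coords <- aperm(coords, c(2, 1, 3))

  hipAxisPt <- posture[10, ]
  hipAxis <- .normalize(posture[13, ] - posture[10, ])
  upAxis <- c(0, 1, 0)

  if (cls == "IDLE") {
    th <- 0.02 * amp * sin(phase(0.25))
    for (f in seq_len(n))
      coords[1:9, , f] <- .rotateAbout(posture[1:9, ], hipAxisPt, hipAxis,
                                       th[f])
  } else if (cls == "ROCKING") {
    th <- 0.30 * amp * sin(phase(1.0))
    for (f in seq_len(n))
      coords[1:9, , f] <- .rotateAbout(posture[1:9, ], hipAxisPt, hipAxis,
                                       th[f])
  } else if (cls == "TURN") {
    th <- 0.80 * amp * sin(phase(0.4))
    idx <- c(1, 2, 4:9)            # torso lies on the rotation axis
    for (f in seq_len(n))
      coords[idx, , f] <- .rotateAbout(posture[idx, ], posture[3, ], upAxis,
                                       th[f])
  } else if (cls == "STANDING") {
    rise <- c(0, 0.42, 0) * subject$scale
    u <- .smoothstep(tt / (0.7 * n))
    L3 <- sqrt(sum((posture[11, ] - posture[10, ])^2))
    L4 <- sqrt(sum((posture[12, ] - posture[11, ])^2))
    dHK0 <- .normalize(posture[11, ] - posture[10, ])
    dKA0 <- .normalize(posture[12, ] - posture[11, ])
    dHK1 <- c(0, -1, 0)
    dKA1 <- .normalize(c(0, -1, 0.05))
    for (f in seq_len(n)) {
      coords[1:9, , f] <- posture[1:9, ] +
        matrix(u[f] * rise, 9, 3, byrow = TRUE)
      for (side in c(0L, 3L)) {    # 0: left leg (10:12), 3: right (13:15)
        hip <- posture[10L + side, ] + u[f] * rise
        knee <- hip + L3 * .blendDir(dHK0, dHK1, u[f])
        ankle <- knee + L4 * .blendDir(dKA0, dKA1, u[f])
        coords[10L + side, , f] <- hip
        coords[11L + side, , f] <- knee
        coords[12L + side, , f] <- ankle
      }
    }
  } else if (cls == "HAND_WAVE") {
    b <- .armDirs(posture, "right")
    d1t <- .normalize(c(-0.55, 0.55, -0.30))
    d2t <- .normalize(c(-0.10, 0.95, -0.20))
    u <- .smoothstep(tt / 8)
    a2 <- 0.45 * amp * sin(phase(4))
    a1 <- 0.12 * amp * sin(phase(4))
    d1 <- t(vapply(seq_len(n), function(f)
      drop(.rotateAbout(rbind(.blendDir(b$d1, d1t, u[f])), c(0, 0, 0),
                        c(0, 0, 1), u[f] * a1[f])), numeric(3)))
    d2 <- t(vapply(seq_len(n), function(f)
      drop(.rotateAbout(rbind(.blendDir(b$d2, d2t, u[f])), c(0, 0, 0),
                        c(0, 0, 1), u[f] * a2[f])), numeric(3)))
    coords <- .setArm(coords, posture, "right", d1, d2)
  } else if (cls == "HAND_RAISE") {
    b <- .armDirs(posture, "right")
    d1t <- .normalize(c(-0.25, 0.90, -0.10))
    d2t <- .normalize(c(0.05, 1.00, 0.00))
    u <- .smoothstep(tt / 10)
    d1 <- t(vapply(seq_len(n), function(f) .blendDir(b$d1, d1t, u[f]),
                   numeric(3)))
    d2 <- t(vapply(seq_len(n), function(f) .blendDir(b$d2, d2t, u[f]),
                   numeric(3)))
    coords <- .setArm(coords, posture, "right", d1, d2)
  } else if (cls == "POINTING") {
    b <- .armDirs(posture, "right")
    d1t <- .normalize(c(-0.15, -0.05, -0.95))
    d2t <- c(0, 0, -1)
    u <- .smoothstep(tt / 10)
    d1 <- t(vapply(seq_len(n), function(f) .blendDir(b$d1, d1t, u[f]),
                   numeric(3)))
    d2 <- t(vapply(seq_len(n), function(f) .blendDir(b$d2, d2t, u[f]),
                   numeric(3)))
    coords <- .setArm(coords, posture, "right", d1, d2)
  } else if (cls == "COVER_EARS") {
    u <- .smoothstep(tt / 10)
    for (side in c("left", "right")) {
      sgn <- if (side == "left") 1 else -1
      b <- .armDirs(posture, side)
      d1t <- .normalize(c(sgn * 0.60, -0.20, -0.40))
      d2t <- .normalize(c(-sgn * 0.75, 0.60, 0.15))
      d1 <- t(vapply(seq_len(n), function(f) .blendDir(b$d1, d1t, u[f]),
                     numeric(3)))
      d2 <- t(vapply(seq_len(n), function(f) .blendDir(b$d2, d2t, u[f]),
                     numeric(3)))
      coords <- .setArm(coords, posture, side, d1, d2)
    }
  } else if (cls == "CLAP") {
    w <- pmin(1, amp * 0.5 * (1 - cos(phase(2))))
    for (side in c("left", "right")) {
      sgn <- if (side == "left") 1 else -1
      b <- .armDirs(posture, side)
      d1t <- .normalize(c(sgn * 0.10, -0.85, -0.50))
      d2t <- .normalize(c(-sgn * 0.90, 0.45, -0.35))
      d1 <- t(vapply(seq_len(n), function(f) .blendDir(b$d1, d1t, w[f]),
                     numeric(3)))
      d2 <- t(vapply(seq_len(n), function(f) .blendDir(b$d2, d2t, w[f]),
                     numeric(3)))
      coords <- .setArm(coords, posture, side, d1, d2)
    }
  }
  # IDLE handled above; every class falls through to viewpoint + noise

  yaw <- switch(viewpoint, front = 0, left = -pi / 2, right = pi / 2)
  if (yaw != 0) {
    hipC <- colMeans(posture[c(10, 13), ])
    for (f in seq_len(n))
      coords[, , f] <- .rotateAbout(coords[, , f], hipC, upAxis, yaw)
  }
  if (subject$sigma > 0) {
    noise <- withr::with_seed(as.integer(seed %% 2147483647), {
      array(stats::rnorm(length(coords), sd = subject$sigma), dim(coords))
    })
    coords <- coords + noise
  }
  SkeletonSequence(coords, subject = sprintf("S%02d", subject$subjectId),
                   label = cls, viewpoint = viewpoint)
}

#' Collection protocol of the synthetic behavior dataset
#'
#' Mirrors the recording protocol being emulated: seated subjects, 9 action
#' classes, and per subject and class 3 frontal samples plus one sample from
#' each side camera placement (left and right), i.e. 45 samples per subject
#' and 1440 samples (160 per class) for the default 32 subjects.
#'
#' @param nSubjects number of subjects (default 32).
#' @param nFrontal,nLeft,nRight samples per subject and class from each
#'   viewpoint (defaults 3, 1, 1).
#' @param nFrames frames per recording (>= 32; default 64 so that windowing
#'   is exercised).
#' @param sigma per-coordinate noise level in meters (default 0.01).
#' @param seed master seed; all subject and sample seeds are derived from
#'   it (see [generateManifest()]).
#' @return a list of class \code{CollectionProtocol}.
#' @export
collectionProtocol <- function(nSubjects = 32L, nFrontal = 3L, nLeft = 1L,
                               nRight = 1L, nFrames = 64L, sigma = 0.01,
                               seed = 1L) {
  stopifnot(nSubjects >= 1, nFrontal >= 0, nLeft >= 0, nRight >= 0,
            nFrames >= 32)
  p <- list(nSubjects = as.integer(nSubjects), nFrontal = as.integer(nFrontal),
            nLeft = as.integer(nLeft), nRight = as.integer(nRight),
            nFrames = as.integer(nFrames), sigma = sigma,
            seed = as.integer(seed))
  class(p) <- "CollectionProtocol"
  p
}

#' Enumerate the samples of a collection protocol
#'
#' Lays out one row per (subject, class, repetition) cell and derives each
#' sample's noise seed from the master seed by a counter scheme:
#' \code{(seed + 100003 * counter) mod (2^31 - 1)}, with the counter running
#' over rows in the listed order. Any individual sample can therefore be
#' regenerated in isolation from its manifest row.
#'
#' @param protocol a [collectionProtocol()].
#' @return data.frame with columns \code{sample_id}, \code{subject},
#'   \code{class}, \code{viewpoint}, \code{seed}.
#' @export
generateManifest <- function(protocol) {
  vps <- c(rep("front", protocol$nFrontal), rep("left", protocol$nLeft),
           rep("right", protocol$nRight))
  grid <- expand.grid(rep = seq_along(vps), class = actionClasses(),
                      subject = seq_len(protocol$nSubjects),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("subject", "class", "rep")]
  counter <- seq_len(nrow(grid)) - 1L
  data.frame(
    sample_id = sprintf("S%02d_%s_%s_%d", grid$subject, grid$class,
                        vps[grid$rep], grid$rep),
    subject = sprintf("S%02d", grid$subject),
    class = grid$class,
    viewpoint = vps[grid$rep],
    seed = as.integer((protocol$seed + 100003 * counter) %% 2147483647),
    stringsAsFactors = FALSE)
}

#' Generate a full labeled synthetic dataset
#'
#' Produces one recording per manifest row of the protocol (default:
#' 32 subjects x 9 classes x 5 samples = 1440 recordings, 160 per class).
#' Deterministic given the protocol's master seed.
#'
#' @param protocol a [collectionProtocol()].
#' @return a [LabeledDataset-class] of [SkeletonSequence-class] samples.
#' @examples
#' ds <- generateDataset(collectionProtocol(nSubjects = 1, seed = 7))
#' length(ds)   # 45
#' @export
generateDataset <- function(protocol = collectionProtocol()) {
  man <- generateManifest(protocol)
  subjects <- lapply(seq_len(protocol$nSubjects), function(i)
    sampleSubject(i, protocol$seed, sigma = protocol$sigma))
  sidx <- as.integer(sub("^S", "", man$subject))
  samples <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    s <- generateAction(man$class[i], subjects[[sidx[i]]], man$viewpoint[i],
                        nFrames = protocol$nFrames, seed = man$seed[i])
    s@sampleId <- man$sample_id[i]
    samples[[i]] <- s
  }
  new("LabeledDataset", samples = samples, label = man$class,
      subject = man$subject, viewpoint = man$viewpoint,
      classes = actionClasses())
}
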