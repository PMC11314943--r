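#' Posture label taxonomies
#'
#' The fine taxonomy has nine labels: supine (S), left/right lateral with
#' legs extended (L.Log / R.Log), half-stomach with bottom leg extended and
#' top leg flexed (L.Sto / R.Sto), fetal with both legs flexed
#' (L.Fet / R.Fet), and prone with the head turned left or right
#' (L.Pr / R.Pr). The coarse taxonomy groups them into Supine / Left /
#' Right / Prone (class sizes 1/3/3/2).
#'
#' @return Character vector of labels in canonical order.
#' @export
posture_levels <- function() {
  c("S", "L.Log", "L.Sto", "L.Fet", "R.Log", "R.Sto", "R.Fet", "L.Pr", "R.Pr")
}

#' @rdname posture_levels
#' @export
coarse_levels <- function() {
  c("Supine", "Left", "Right", "Prone")
}

#' Map fine posture labels to coarse classes
#'
#' S maps to Supine; L.Log/L.Sto/L.Fet to Left; R.Log/R.Sto/R.Fet to Right;
#' L.Pr/R.Pr to Prone.
#'
#' @param fine Character or factor vector of fine labels.
#' @return Factor of coarse labels with levels `coarse_levels()`.
#' @examples
#' coarse_map(c("S", "L.Sto", "R.Pr"))
#' @export
coarse_map <- function(fine) {
  fine <- as.character(fine)
  bad <- setdiff(unique(fine), posture_levels())
  if (length(bad)) {
    stop("unknown posture label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lut <- c(S = "Supine",
           L.Log = "Left", L.Sto = "Left", L.Fet = "Left",
           R.Log = "Right", R.Sto = "Right", R.Fet = "Right",
           L.Pr = "Prone", R.Pr = "Prone")
  factor(unname(lut[fine]), levels = coarse_levels())
}

# Base scatterer layout for a body on its back, bed-frame cm.
# Columns: x, y, reflectivity. Midline x = 45, head towards y = 0.
supine_template <- function() {
  rbind(
    head      = c(45, 20, 0.8),
    shoulderL = c(29, 38, 1.0),  # subject's right is bed-left under supine
    shoulderR = c(61, 38, 1.0),
    chest     = c(45, 55, 1.5),
    abdomen   = c(45, 75, 1.3),
    hipL      = c(36, 95, 1.2),
    hipR      = c(54, 95, 1.2),
    kneeL     = c(38, 135, 0.7),
    kneeR     = c(52, 135, 0.7),
    footL     = c(39, 172, 0.5),
    footR     = c(51, 172, 0.5)
  )
}

# Left-handed variants; right-sided postures are exact mirrors about the
# bed midline (x = 45), applied after jitter so mirror pairs share draws.
left_template <- function(variant = c("log", "sto", "fet")) {
  variant <- match.arg(variant)
  m <- supine_template()
  # roll onto the left side: lateral compression towards a line left of
  # midline, stacked shoulders/hips present a taller cross-section to the
  # side radars (higher reflectivity on torso points)
  mid <- 45
  m[, 1] <- mid - 8 + (m[, 1] - mid) * 0.45
  m[c("shoulderL", "shoulderR", "hipL", "hipR"), 3] <-
    m[c("shoulderL", "shoulderR", "hipL", "hipR"), 3] * 1.2
  flex <- function(m, knee, foot) {
    # pull the flexed leg cranially and towards the front of the body
    m[knee, 2] <- m[knee, 2] - 22
    m[knee, 1] <- m[knee, 1] - 6
    m[foot, 2] <- m[knee, 2] + 12
    m[foot, 1] <- m[knee, 1] + 2
    m
  }
  if (variant == "fet") {
    m <- flex(m, "kneeL", "footL")
    m <- flex(m, "kneeR", "footR")
  } else if (variant == "sto") {
    # bottom leg extended, top leg flexed
    m <- flex(m, "kneeR", "footR")
    # torso rolls partly towards prone
    m[c("chest", "abdomen"), 3] <- m[c("chest", "abdomen"), 3] * 0.9
  }
  m
}

prone_template <- function(head_turn = c("left", "right")) {
  head_turn <- match.arg(head_turn)
  m <- supine_template()
  # back faces up: weaker torso return, head offset by the turn
  m[c("chest", "abdomen"), 3] <- m[c("chest", "abdomen"), 3] * 0.7
  m["head", 1] <- m["head", 1] + if (head_turn == "left") -6 else 6
  m
}

#' Build a posture phantom
#'
#' Generates a parametric scatterer template for one of the nine sleep
#' postures, scaled to the subject and perturbed by positional jitter.
#' Left/right posture pairs are exact mirror images about the bed midline
#' (x = 45 cm) when generated from the same RNG state: the left-handed
#' canonical template is jittered first and then mirrored for right-sided
#' labels, so the paired draws coincide.
#'
#' @param posture One of `posture_levels()`.
#' @param subject_scale List with `height` and `width` multipliers
#'   (1 = the 172 cm reference body).
#' @param jitter_sd Positional jitter standard deviation, cm.
#' @return An object of class `phantom`: fields `posture`, `scatterers`
#'   (matrix with columns x, y, reflectivity), `subject_scale`.
#' @export
make_phantom <- function(posture,
                         subject_scale = list(height = 1, width = 1),
                         jitter_sd = 1.5) {
  if (!posture %in% posture_levels()) {
    stop("unknown posture label: ", posture, call. = FALSE)
  }
  base <- switch(posture,
    "S"     = supine_template(),
    "L.Log" = left_template("log"),
    "R.Log" = left_template("log"),
    "L.Sto" = left_template("sto"),
    "R.Sto" = left_template("sto"),
    "L.Fet" = left_template("fet"),
    "R.Fet" = left_template("fet"),
    "L.Pr"  = prone_template("left"),
    "R.Pr"  = prone_template("right")
  )
  mid <- 45
  base[, 1] <- mid + (base[, 1] - mid) * subject_scale$width
  base[, 2] <- base[, 2] * subject_scale$height
  n <- nrow(base)
  base[, 1] <- base[, 1] + stats::rnorm(n, 0, jitter_sd)
  base[, 2] <- base[, 2] + stats::rnorm(n, 0, jitter_sd)
  # mirror right-sided lateral/fetal/half-stomach after jitter; prone
  # templates are intrinsically handed via the head turn
  if (posture %in% c("R.Log", "R.Sto", "R.Fet")) {
    base[, 1] <- 2 * mid - base[, 1]
  }
  base[, 1:2] <- pmin(pmax(base[, 1:2], -50), 250)
  colnames(base) <- c("x", "y", "reflectivity")
  structure(
    list(posture = posture, scatterers = base, subject_scale = subject_scale),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %s> %d scatterers, y-extent %.1f cm\n",
              x$posture, nrow(x$scatterers),
              diff(range(x$scatterers[, "y"]))))
  invisible(x)
}
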