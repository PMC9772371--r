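## Stimulus construction.  Every display lives in a 9 x 9 cm frame rendered
## to a square raster; layouts are expressed as ordered lists of filled
## axis-aligned rectangles in cm coordinates (x rightward, y downward,
## origin top-left).  Rectangles are painted back-to-front; a pixel belongs
## to a rectangle when its centre falls inside it, so images contain only
## the exact palette luminances (no anti-aliasing).

ROLE_BG <- 0L
ROLE_LEFT <- 1L
ROLE_RIGHT <- 2L

rect <- function(x0, x1, y0, y1, lum, role = ROLE_BG) {
  list(x0 = x0, x1 = x1, y0 = y0, y1 = y1, lum = lum, role = role)
}

mirror_rect <- function(r) {
  role <- if (r$role == ROLE_LEFT) ROLE_RIGHT
          else if (r$role == ROLE_RIGHT) ROLE_LEFT
          else ROLE_BG
  rect(FRAME_CM - r$x1, FRAME_CM - r$x0, r$y0, r$y1, r$lum, role)
}

## pixel range [j0, j1] of pixels whose centre (j - 0.5)/s cm lies in
## [x0, x1); boundaries exactly on a centre go to the rectangle on the right
px_range <- function(x0, x1, s) {
  j0 <- ceiling(x0 * s + 0.5 - 1e-9)
  j1 <- ceiling(x1 * s + 0.5 - 1e-9) - 1
  c(max(1L, as.integer(j0)), as.integer(j1))
}

paint <- function(img, id, rects, s) {
  n <- nrow(img)
  for (r in rects) {
    cx <- px_range(r$x0, r$x1, s)
    cy <- px_range(r$y0, r$y1, s)
    cx[2] <- min(cx[2], n); cy[2] <- min(cy[2], n)
    if (cx[2] < cx[1] || cy[2] < cy[1]) next
    img[cy[1]:cy[2], cx[1]:cx[2]] <- r$lum
    id[cy[1]:cy[2], cx[1]:cx[2]] <- r$role
  }
  list(img = img, id = id)
}

## ---- per-display layouts (lists of rects, painted in order) -------------

layout_slc <- function(target_lum = LUM_GRAY, extras = list()) {
  tl <- rect(1.15, 3.35, 3.4, 5.6, target_lum, ROLE_LEFT)
  c(list(
    rect(0, 4.5, 0, 9, LUM_BLACK),
    rect(4.5, 9, 0, 9, LUM_WHITE)
  ), extras, list(tl, mirror_rect(tl)))
}

layout_maniatis <- function() {
  ## SLC plus one white square, same size as the target, in the upper-left
  ## corner quadrant of the black half (not adjacent to the target)
  layout_slc(extras = list(rect(0.2, 2.4, 0.2, 2.4, LUM_WHITE)))
}

layout_whites <- function(n_stripes = 8) {
  w <- FRAME_CM / n_stripes
  stripes <- lapply(seq_len(n_stripes), function(k) {
    first_black <- n_stripes == 8   # 4-stripe variant starts white
    black <- if (first_black) k %% 2 == 1 else k %% 2 == 0
    rect((k - 1) * w, k * w, 0, 9, if (black) LUM_BLACK else LUM_WHITE)
  })
  ## targets span the full stripe width (the printed sizes 1.1 / 2.2 cm are
  ## the stripe widths 9/8 and 9/4 cm rounded), so the target is an exact
  ## collinear segment of its stripe
  if (n_stripes == 8) {
    tw <- w; cx <- 2.5 * w + w / 2     # stripe 3, black
  } else {
    tw <- w; cx <- 1 * w + w / 2       # stripe 2, black
  }
  tl <- rect(cx - tw / 2, cx + tw / 2, 3.4, 5.6, LUM_GRAY, ROLE_LEFT)
  c(stripes, list(tl, mirror_rect(tl)))
}

layout_wedding_cake <- function() {
  ## interleaved stair-step bands 0.5 cm thick; the band pattern shifts
  ## down by 0.5 cm every 1.5 cm of horizontal run, giving a staircase
  ## with flat runs long enough to hold the 1.5 cm target bars and no
  ## T-junctions along the band contours
  rects <- list()
  zig <- c(0, 0.5, 1, 0.5, 0, 0.5)       # triangle-wave step offsets
  for (j in 0:5) {
    x0 <- 1.5 * j; off <- zig[j + 1]
    for (k in -2:20) {
      y0 <- 0.5 * k - off
      lum <- if (k %% 2 == 0) LUM_BLACK else LUM_WHITE
      rects[[length(rects) + 1L]] <- rect(x0, x0 + 1.5, y0, y0 + 0.5, lum)
    }
  }
  ## left target continues a black band step, right target a white one
  tl <- rect(1.5, 3.0, 4.5, 5.0, LUM_GRAY, ROLE_LEFT)
  tr <- rect(6.0, 7.5, 4.5, 5.0, LUM_GRAY, ROLE_RIGHT)
  c(rects, list(tl, tr))
}

layout_reversed_contrast <- function() {
  ## thin horizontal target bars flanked above and below by bars of the
  ## polarity opposite to the half-field background (two flankers per side,
  ## 0.3 cm gaps)
  rects <- list(
    rect(0, 4.5, 0, 9, LUM_BLACK),
    rect(4.5, 9, 0, 9, LUM_WHITE)
  )
  ys <- 4.5 + c(-1.2, -0.6, 0.6, 1.2)
  for (yc in ys) {
    fl <- rect(1.15, 3.35, yc - 0.15, yc + 0.15, LUM_WHITE)
    rects <- c(rects, list(fl, mirror_rect(rect(fl$x0, fl$x1, fl$y0, fl$y1,
                                                LUM_BLACK))))
  }
  tl <- rect(1.15, 3.35, 4.35, 4.65, LUM_GRAY, ROLE_LEFT)
  c(rects, list(tl, mirror_rect(tl)))
}

layout_dungeon <- function() {
  ## a thin white lattice "net" (0.1 cm lines, 0.75 cm windows) over the
  ## black left half, mirrored black net over the white right half; the
  ## windows show the background, and the central window holds the grey
  ## target cell inset by a background margin -- seen through the net,
  ## with the background as its immediate surround
  line <- 0.1; hole <- 0.75; n_cells <- 5
  block <- n_cells * hole + (n_cells + 1) * line   # 4.35 cm
  bx <- (4.5 - block) / 2
  by <- 4.5 - block / 2
  rects <- list(
    rect(0, 4.5, 0, 9, LUM_BLACK),
    rect(4.5, 9, 0, 9, LUM_WHITE),
    rect(bx, bx + block, by, by + block, LUM_WHITE),
    rect(9 - bx - block, 9 - bx, by, by + block, LUM_BLACK)
  )
  mid <- (n_cells + 1L) %/% 2L
  for (i in seq_len(n_cells)) {
    for (j in seq_len(n_cells)) {
      x0 <- bx + line + (hole + line) * (i - 1)
      y0 <- by + line + (hole + line) * (j - 1)
      h <- rect(x0, x0 + hole, y0, y0 + hole, LUM_BLACK)
      rects <- c(rects, list(h, mirror_rect(rect(h$x0, h$x1, h$y0, h$y1,
                                                 LUM_WHITE))))
      if (i == mid && j == mid) {
        m <- (hole - 0.5) / 2
        tl <- rect(x0 + m, x0 + m + 0.5, y0 + m, y0 + m + 0.5,
                   LUM_GRAY, ROLE_LEFT)
        rects <- c(rects, list(tl, mirror_rect(tl)))
      }
    }
  }
  rects
}

layout_checkerboard <- function() {
  ## 9 x 9 checks of 1 cm; the left grey check replaces a white check (all
  ## four neighbours black), the right one a black check (all neighbours
  ## white) -- with an odd check count the two parities cannot sit at
  ## mirrored positions, so the right target is offset by one row
  rects <- list()
  for (r in 1:9) {
    for (cc in 1:9) {
      lum <- if ((r + cc) %% 2 == 1) LUM_BLACK else LUM_WHITE
      rects[[length(rects) + 1L]] <- rect(cc - 1, cc, r - 1, r, lum)
    }
  }
  tl <- rect(2, 3, 4, 5, LUM_GRAY, ROLE_LEFT)    # row 5, col 3 (white)
  tr <- rect(6, 7, 3, 4, LUM_GRAY, ROLE_RIGHT)   # row 4, col 7 (black)
  c(rects, list(tl, tr))
}

layout_bullseye <- function() {
  ## per half: a central vertical 0.5 x 5 cm grey bar surrounded by four
  ## concentric 0.5 cm rectangular rings, which tile the 4.5 x 9 cm half
  ## exactly; the innermost ring is black on the left and white on the
  ## right ("surrounded by black vs white inducers")
  ring <- function(cx, k, lum) {
    ## ring k (1 = innermost) around a 0.5 x 5 bar centred at (cx, 4.5)
    rect(cx - 0.25 - 0.5 * k, cx + 0.25 + 0.5 * k,
         2 - 0.5 * k, 7 + 0.5 * k, lum)
  }
  rects <- list()
  for (k in 4:1) {
    lum_left <- if (k %% 2 == 1) LUM_BLACK else LUM_WHITE
    lum_right <- if (k %% 2 == 1) LUM_WHITE else LUM_BLACK
    rects <- c(rects, list(ring(2.25, k, lum_left),
                           ring(6.75, k, lum_right)))
  }
  tl <- rect(2, 2.5, 2, 7, LUM_GRAY, ROLE_LEFT)
  tr <- rect(6.5, 7, 2, 7, LUM_GRAY, ROLE_RIGHT)
  c(rects, list(tl, tr))
}

## seeded guillotine tessellation for the Mondrians: repeatedly split the
## largest rectangle along its longer side until n_surfaces pieces exist
layout_mondrian <- function(n_surfaces) {
  parts <- list(c(0, 9, 0, 9))
  while (length(parts) < n_surfaces) {
    areas <- vapply(parts, function(p) (p[2] - p[1]) * (p[4] - p[3]), 0)
    i <- which.max(areas)
    p <- parts[[i]]
    f <- stats::runif(1, 0.35, 0.65)
    if ((p[2] - p[1]) >= (p[4] - p[3])) {
      cut <- p[1] + f * (p[2] - p[1])
      new <- list(c(p[1], cut, p[3], p[4]), c(cut, p[2], p[3], p[4]))
    } else {
      cut <- p[3] + f * (p[4] - p[3])
      new <- list(c(p[1], p[2], p[3], cut), c(p[1], p[2], cut, p[4]))
    }
    parts <- c(parts[-i], new)
  }
  ## luminances: uniform over [6, 145] cd/m2, quantized to the 8-bit gray
  ## levels of the calibration map; redraw when edge-sharing neighbours get
  ## the same level
  lums <- mondrian_luminances(parts)
  rects <- mapply(function(p, L) rect(p[1], p[2], p[3], p[4], L),
                  parts, lums, SIMPLIFY = FALSE)
  tl <- rect(1.15, 3.35, 3.4, 5.6, LUM_GRAY, ROLE_LEFT)
  c(rects, list(tl, mirror_rect(tl)))
}

mondrian_luminances <- function(parts) {
  n <- length(parts)
  draw <- function() {
    g <- round(luminance_to_gray(stats::runif(1, 6, 145)))
    gray_to_luminance(g)
  }
  lums <- vapply(seq_len(n), function(i) draw(), 0)
  touches <- function(a, b) {
    shared_v <- (abs(a[2] - b[1]) < 1e-9 || abs(b[2] - a[1]) < 1e-9) &&
      (min(a[4], b[4]) - max(a[3], b[3]) > 1e-9)
    shared_h <- (abs(a[4] - b[3]) < 1e-9 || abs(b[4] - a[3]) < 1e-9) &&
      (min(a[2], b[2]) - max(a[1], b[1]) > 1e-9)
    shared_v || shared_h
  }
  for (pass in 1:100) {
    clash <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (abs(lums[i] - lums[j]) < 1e-9 && touches(parts[[i]], parts[[j]])) {
          lums[j] <- draw(); clash <- TRUE
        }
      }
    }
    if (!clash) break
  }
  lums
}

display_layout <- function(name) {
  switch(name,
    slc = layout_slc(),
    slc_dark = layout_slc(LUM_DARK_TARGET),
    slc_light = layout_slc(LUM_LIGHT_TARGET),
    maniatis = layout_maniatis(),
    whites = layout_whites(8),
    whites_large = layout_whites(4),
    wedding_cake = layout_wedding_cake(),
    reversed_contrast = layout_reversed_contrast(),
    dungeon = layout_dungeon(),
    checkerboard = layout_checkerboard(),
    bullseye = layout_bullseye(),
    mondrian4 = layout_mondrian(4),
    mondrian34 = layout_mondrian(34),
    stop("unknown display '", name, "'; see list_displays()")
  )
}

min_feature_cm <- function(name) {
  switch(name,
    whites = 1.1, whites_large = 2.2, wedding_cake = 0.5,
    reversed_contrast = 0.3, dungeon = 0.1, checkerboard = 1,
    bullseye = 0.5, 2.2)
}

#' Build a benchmark display as a calibrated luminance image
#'
#' Renders one of the 13 catalogue displays (see [list_displays()]) to a
#' square luminance raster with boolean masks for the left and right
#' targets.  The frame is 9 x 9 cm; `resolution` pixels span the frame, so
#' `px_per_cm = resolution / 9`.  Illusion images contain only the exact
#' palette luminances (6, 69, 145 cd/m2, plus 25 or 105 for the SLC
#' luminance variants); Mondrians draw their surface luminances from a
#' seeded uniform distribution over 6-145 cd/m2 quantized to 8-bit gray
#' levels.
#'
#' @param name display identifier, one of `list_displays()$name`.
#' @param resolution pixels per frame side (>= 64; default 512).
#' @param ppd pixels per degree of visual angle carried as metadata for the
#'   filter models (default 32, i.e. the 9 cm frame subtends 16 deg).
#' @param seed integer; required for the Mondrian displays, ignored
#'   otherwise.
#' @return an object of class `stimulus_bundle`: a list with `image`
#'   (resolution x resolution luminance matrix, cd/m2), `mask_left`,
#'   `mask_right` (logical matrices), `name`, `px_per_cm`, `ppd`,
#'   `target_luminance`, and `target_diameter_px` (the smaller printed
#'   target dimension in pixels, rounded to an odd integer -- the default
#'   high-pass filter size).
#' @export
#' @examples
#' b <- build_display("slc", resolution = 128)
#' sort(unique(as.vector(b$image)))
build_display <- function(name, resolution = 512, ppd = 32, seed = NULL) {
  info <- display_info(name)
  if (!is.numeric(resolution) || resolution < 64) {
    stop("resolution must be at least 64 pixels")
  }
  resolution <- as.integer(resolution)
  s <- resolution / FRAME_CM
  if (min_feature_cm(name) * s < 1) {
    stop("resolution ", resolution, " too small to render the finest ",
         "element of '", name, "' (", min_feature_cm(name), " cm) at >= 1 px")
  }
  if (info$needs_seed && is.null(seed)) {
    stop("display '", name, "' is randomized and requires a seed")
  }
  layout <- if (info$needs_seed) {
    with_seed(as.integer(seed), display_layout(name))
  } else {
    display_layout(name)
  }
  img <- matrix(NA_real_, resolution, resolution)
  id <- matrix(ROLE_BG, resolution, resolution)
  out <- paint(img, id, layout, s)
  stopifnot(!anyNA(out$img))
  mask_left <- out$id == ROLE_LEFT
  mask_right <- out$id == ROLE_RIGHT
  stopifnot(any(mask_left), any(mask_right))
  tpx <- round(min(info$target_w_cm, info$target_h_cm) * s)
  if (tpx %% 2 == 0) tpx <- tpx + 1L
  structure(
    list(image = out$img, mask_left = mask_left, mask_right = mask_right,
         name = name, px_per_cm = s, ppd = ppd,
         target_luminance = info$target_luminance,
         target_diameter_px = as.integer(tpx),
         human_sign = info$human_sign, seed = seed),
    class = "stimulus_bundle")
}

#' @export
print.stimulus_bundle <- function(x, ...) {
  cat("<stimulus_bundle> ", x$name, ": ", nrow(x$image), "x", ncol(x$image),
      " px, ", round(x$px_per_cm, 2), " px/cm, ppd ", x$ppd, "\n",
      "  luminances: ", paste(sort(unique(round(as.vector(x$image), 3)))[
        seq_len(min(8, length(unique(as.vector(x$image)))))], collapse = ", "),
      if (length(unique(as.vector(x$image))) > 8) " ..." else "", " cd/m2\n",
      "  target px: left ", sum(x$mask_left), ", right ", sum(x$mask_right),
      "\n", sep = "")
  invisible(x)
}

## evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
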