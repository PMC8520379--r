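#' Coarse descriptor matching with the nearest-neighbour ratio test
#'
#' For each source descriptor, the nearest and second-nearest target
#' descriptors by Euclidean distance are found; the match is kept when
#' `d1/d2 < ratio`.  Degenerate (all-zero) descriptors never match.
#' One-to-one assignment is enforced by keeping only the smallest-distance
#' claim on each target keypoint.
#'
#' @param src_kps,dst_kps Keypoint data frames (need columns `x`, `y`).
#' @param src_desc,dst_desc Descriptor matrices aligned with the keypoints.
#' @param ratio Nearest/second-nearest distance ratio threshold (default 0.8).
#' @return Match data frame with columns `src_idx`, `dst_idx`, `src_x`,
#'   `src_y`, `dst_x`, `dst_y`, `distance`, `slope` (`NA` until
#'   [composite_slopes()]) and `status` (`"coarse"`).
#' @export
coarse_match <- function(src_kps, dst_kps, src_desc, dst_desc, ratio = 0.8) {
  stopifnot(nrow(src_kps) == nrow(src_desc), nrow(dst_kps) == nrow(dst_desc))
  ok_s <- rowSums(src_desc^2) > 0
  ok_d <- rowSums(dst_desc^2) > 0
  if (!any(ok_s) || !any(ok_d)) {
    warning("all descriptors degenerate; no matches", call. = FALSE)
    return(empty_matches())
  }
  si <- which(ok_s); di <- which(ok_d)
  A <- src_desc[si, , drop = FALSE]
  B <- dst_desc[di, , drop = FALSE]
  # squared Euclidean distances via the polarization identity
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  keep_src <- integer(0); keep_dst <- integer(0); keep_d <- numeric(0)
  for (i in seq_along(si)) {
    row <- d2[i, ]
    j1 <- which.min(row)
    d1 <- row[j1]
    if (length(row) < 2L) next
    d2nd <- min(row[-j1])
    if (sqrt(d1) < ratio * sqrt(d2nd)) {
      keep_src <- c(keep_src, si[i])
      keep_dst <- c(keep_dst, di[j1])
      keep_d <- c(keep_d, sqrt(d1))
    }
  }
  if (length(keep_src) == 0L) return(empty_matches())
  m <- data.frame(
    src_idx = keep_src, dst_idx = keep_dst,
    src_x = src_kps$x[keep_src], src_y = src_kps$y[keep_src],
    dst_x = dst_kps$x[keep_dst], dst_y = dst_kps$y[keep_dst],
    distance = keep_d, slope = NA_real_, status = "coarse",
    stringsAsFactors = FALSE
  )
  # one-to-one: smallest distance wins each contested target keypoint
  m <- m[order(m$distance, m$src_idx), ]
  m <- m[!duplicated(m$dst_idx), ]
  m <- m[order(m$src_idx), ]
  rownames(m) <- NULL
  m
}

empty_matches <- function() {
  data.frame(
    src_idx = integer(0), dst_idx = integer(0),
    src_x = numeric(0), src_y = numeric(0),
    dst_x = numeric(0), dst_y = numeric(0),
    distance = numeric(0), slope = numeric(0),
    status = character(0), stringsAsFactors = FALSE
  )
}

#' Parameters of the slope-consistency pre-check
#'
#' @param t Neighbourhood threshold in slope units (default 0.02, the
#'   empirical value).
#' @param composite_offset Horizontal shift applied to target-frame x
#'   coordinates when both frames are placed side by side in one composite
#'   coordinate system; must be at least the source-image width so every
#'   match line has strictly positive run and hence a finite slope.
#' @return A `prescreen_params` list.
#' @export
prescreen_params <- function(t = 0.02, composite_offset) {
  stopifnot(is.numeric(t), t > 0, is.numeric(composite_offset))
  structure(list(t = t, composite_offset = composite_offset),
            class = "prescreen_params")
}

#' Compute composite-frame match-line slopes
#'
#' Places the two frames in one coordinate system by shifting the target
#' frame right by `composite_offset` and computes, for every match, the slope
#' of the straight line joining the source keypoint to its (shifted) target
#' keypoint: `k = (dst_y - src_y) / (dst_x + offset - src_x)`.
#'
#' @param matches Match data frame from [coarse_match()].
#' @param params A [prescreen_params()]; `composite_offset` must be `>=` the
#'   source-image width (checked against `src_width` when given).
#' @param src_width Optional source-image width used to validate the offset.
#' @return The match data frame with `slope` filled in.
#' @export
composite_slopes <- function(matches, params, src_width = NULL) {
  stopifnot(inherits(params, "prescreen_params"))
  if (!is.null(src_width) && params$composite_offset < src_width) {
    stop("composite_offset (", params$composite_offset,
         ") must be at least the source image width (", src_width, ")",
         call. = FALSE)
  }
  if (nrow(matches) == 0L) return(matches)
  run <- (matches$dst_x + params$composite_offset) - matches$src_x
  if (any(run <= 0)) {
    stop("composite_offset too small: some match lines have non-positive run",
         call. = FALSE)
  }
  matches$slope <- (matches$dst_y - matches$src_y) / run
  matches
}

#' Slope-consistency pre-check (pre-inspection strategy)
#'
#' Loops over the entire coarse match set: every match's slope `k_i` is a
#' candidate neighbourhood centre, and its census is the number of matches
#' `j` with `|k_j - k_i| <= t`.  The centre with the maximal census wins
#' (ties broken toward the smaller `|k_i|`, then the lower source index,
#' so the result is order-invariant); matches inside the winning
#' neighbourhood become `preselected`, all others `rejected_slope`.
#'
#' With fewer than 3 matches the census is meaningless and the input is
#' passed through unchanged with a warning.
#'
#' @param matches Match data frame with slopes ([composite_slopes()]).
#' @param params A [prescreen_params()].
#' @return The match data frame with updated `status`; attribute
#'   `winning_slope` records the selected centre.
#' @export
prescreen <- function(matches, params) {
  stopifnot(inherits(params, "prescreen_params"))
  if (nrow(matches) < 3L) {
    warning("fewer than 3 coarse matches; slope pre-check skipped",
            call. = FALSE)
    if (nrow(matches) > 0L) matches$status <- "preselected"
    return(matches)
  }
  if (anyNA(matches$slope)) {
    stop("slopes not computed; call composite_slopes() first", call. = FALSE)
  }
  k <- matches$slope
  census <- vapply(k, function(ki) sum(abs(k - ki) <= params$t), integer(1))
  best <- max(census)
  cand <- which(census == best)
  # deterministic tie-break: smallest |centre slope|, then lowest src index
  ord <- order(abs(k[cand]), matches$src_idx[cand])
  win <- cand[ord[1L]]
  inside <- abs(k - k[win]) <= params$t
  matches$status <- ifelse(inside, "preselected", "rejected_slope")
  attr(matches, "winning_slope") <- k[win]
  matches
}

#' Disparity gradient between two matches
#'
#' With disparity vectors `d(m) = dst - src` (raw image frames, no composite
#' offset) and cyclopean midpoints `c(m) = (src + dst) / 2`, the disparity
#' gradient is `||d(m) - d(n)|| / ||c(m) - c(n)||`.  Mutually consistent
#' matches on a smooth surface have small gradients; the retention rule used
#' downstream is the classical bound `gradient < 2`.  Returns `Inf` when the
#' midpoints coincide.
#'
#' @param m,n Single-row match data frames (or lists with `src_x`, `src_y`,
#'   `dst_x`, `dst_y`).
#' @return Non-negative scalar (possibly `Inf`).
#' @export
disparity_gradient <- function(m, n) {
  if (isTRUE(all.equal(c(m$src_x, m$src_y, m$dst_x, m$dst_y),
                       c(n$src_x, n$src_y, n$dst_x, n$dst_y)))) {
    stop("disparity gradient of a match with itself is undefined",
         call. = FALSE)
  }
  dm <- c(m$dst_x - m$src_x, m$dst_y - m$src_y)
  dn <- c(n$dst_x - n$src_x, n$dst_y - n$src_y)
  cm <- c(m$src_x + m$dst_x, m$src_y + m$dst_y) / 2
  cn <- c(n$src_x + n$dst_x, n$src_y + n$dst_y) / 2
  sep <- sqrt(sum((cm - cn)^2))
  if (sep == 0) return(Inf)
  sqrt(sum((dm - dn)^2)) / sep
}

#' Disparity-gradient mismatch filter
#'
#' Operationalizes the adjacency requirement with K-nearest neighbours:
#' each preselected match is compared with its `K` nearest preselected
#' neighbours by source-image Euclidean distance, and retained iff the median
#' of those disparity gradients is strictly below `dg_max` (default 2).
#'
#' When fewer than `K + 1` preselected matches exist, `K` is reduced to the
#' available count minus one; with fewer than 2 matches the filter is
#' undefined and input passes through with a warning.
#'
#' @param matches Match data frame; only rows with status `preselected` are
#'   tested, others keep their status.
#' @param K Number of source-space nearest neighbours (default 4).
#' @param dg_max Strict upper bound on the median neighbour gradient
#'   (default 2).
#' @return The match data frame with preselected rows promoted to `retained`
#'   or demoted to `rejected_disparity`.
#' @export
disparity_filter <- function(matches, K = 4L, dg_max = 2) {
  pre <- which(matches$status == "preselected")
  n <- length(pre)
  if (n < 2L) {
    warning("fewer than 2 preselected matches; disparity filter skipped",
            call. = FALSE)
    matches$status[pre] <- "retained"
    return(matches)
  }
  K <- min(K, n - 1L)
  sx <- matches$src_x[pre]; sy <- matches$src_y[pre]
  dxv <- matches$dst_x[pre] - sx; dyv <- matches$dst_y[pre] - sy
  cx <- sx + dxv / 2; cy <- sy + dyv / 2
  keep <- logical(n)
  for (i in seq_len(n)) {
    dist2 <- (sx - sx[i])^2 + (sy - sy[i])^2
    ord <- order(dist2, seq_len(n))       # index tie-break: deterministic
    nbrs <- setdiff(ord, i)[seq_len(K)]
    sep <- sqrt((cx[nbrs] - cx[i])^2 + (cy[nbrs] - cy[i])^2)
    dd <- sqrt((dxv[nbrs] - dxv[i])^2 + (dyv[nbrs] - dyv[i])^2)
    grad <- ifelse(sep == 0, Inf, dd / sep)
    keep[i] <- stats::median(grad) < dg_max
  }
  matches$status[pre[keep]] <- "retained"
  matches$status[pre[!keep]] <- "rejected_disparity"
  matches
}

#' Run both mismatch filters in sequence
#'
#' Computes composite-frame slopes, applies the slope-consistency pre-check
#' and then the disparity-gradient filter.
#'
#' @param matches Coarse match data frame.
#' @param src_width Width of the source image (sets the composite offset).
#' @param t Slope neighbourhood threshold.
#' @param K,dg_max Disparity-filter parameters.
#' @return Filtered match data frame (statuses `retained`, `rejected_slope`,
#'   `rejected_disparity`), with attribute `winning_slope`.
#' @export
filter_matches <- function(matches, src_width, t = 0.02, K = 4L, dg_max = 2) {
  params <- prescreen_params(t = t, composite_offset = src_width)
  m <- composite_slopes(matches, params, src_width = src_width)
  m <- prescreen(m, params)
  ws <- attr(m, "winning_slope")
  m <- disparity_filter(m, K = K, dg_max = dg_max)
  attr(m, "winning_slope") <- ws
  m
}

#' Summarize filter outcomes as a report list
#'
#' @param matches Filtered match data frame.
#' @param params Optional parameter list echoed into the report.
#' @return List with per-status counts, the winning slope centre and the
#'   parameters used; serializes cleanly to JSON.
#' @export
filter_report <- function(matches, params = NULL) {
  counts <- as.list(table(factor(
    matches$status,
    levels = c("coarse", "preselected", "retained",
               "rejected_slope", "rejected_disparity")
  )))
  counts <- lapply(counts, as.integer)
  list(
    n_matches = nrow(matches),
    counts = counts,
    winning_slope = attr(matches, "winning_slope"),
    params = params
  )
}

#' Write matches to CSV
#'
#' Columns: `src_x,src_y,dst_x,dst_y,distance,slope,status`.
#'
#' @param matches Match data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  utils::write.csv(
    matches[, c("src_x", "src_y", "dst_x", "dst_y",
                "distance", "slope", "status")],
    path, row.names = FALSE
  )
  invisible(path)
}
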