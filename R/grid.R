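## 24-2 test-point lattice, right-eye orientation. Rows top to bottom,
## points left to right within a row (standard HFA reading order); the two
## physiologic blind-spot points are ids 26 and 35 at (15, +/-3) degrees.
.grid242_layout <- function() {
  rows <- list(
    list(y = 21,  x = seq(-9, 9, by = 6)),
    list(y = 15,  x = seq(-15, 15, by = 6)),
    list(y = 9,   x = seq(-21, 21, by = 6)),
    list(y = 3,   x = seq(-27, 21, by = 6)),
    list(y = -3,  x = seq(-27, 21, by = 6)),
    list(y = -9,  x = seq(-21, 21, by = 6)),
    list(y = -15, x = seq(-15, 15, by = 6)),
    list(y = -21, x = seq(-9, 9, by = 6))
  )
  x <- unlist(lapply(rows, `[[`, "x"))
  y <- unlist(lapply(rows, function(r) rep(r$y, length(r$x))))
  data.frame(location_id = seq_along(x), x = x, y = y,
             is_blind_spot = (x == 15 & abs(y) == 3))
}

## Optic-disc entry angles for the retained points. This is a synthetic,
## anatomically motivated stand-in for the published structure-function
## entry-angle map (which is not redistributable here): nerve-fibre bundles
## are modelled as arcs around the optic nerve head at (15, 2) degrees, with
## the temporal raphe splitting fibres just above/below the horizontal into
## superior and inferior arcades that enter the disc at least 20 degrees
## from the temporal pole. Angles are degrees in [0, 360), 0 = temporal
## pole, increasing through superior (90) and nasal (180) to inferior (270).
.gh_entry_angle <- function(x, y, onh = c(15, 2), raphe_offset = 20) {
  dx <- x - onh[1]
  dy <- y - onh[2]
  beta <- atan2(abs(dy), dx) * 180 / pi        # [0, 180]: temporal -> nasal
  entry <- raphe_offset + (180 - raphe_offset) * beta / 180
  ifelse(dy >= 0, entry, (360 - entry) %% 360)
}

#' Build the 24-2 visual-field grid
#'
#' Constructs the standard Humphrey 24-2 lattice (54 points, right-eye
#' orientation) with its 2 blind-spot exclusions, optic-disc entry angles
#' for the 52 retained points, an adjacency graph and the anatomical
#' dissimilarity of each adjacent pair (see [pairDissimilarity()]).
#'
#' Adjacency is defined on the 6-degree lattice: \code{"rook"} joins points
#' 6 degrees apart horizontally or vertically; \code{"queen"} (default)
#' additionally joins diagonal neighbours at distance \eqn{6\sqrt{2}}.
#' Blind-spot points take part in no pair.
#'
#' The packaged entry-angle table is a synthetic anatomically motivated
#' approximation of the published structure-function map (see the package
#' vignette); analyses that need the published angles can substitute them
#' via \code{gh_angle}.
#'
#' @param adjacencyRule \code{"queen"} or \code{"rook"}.
#' @param gh_angle optional replacement entry angles: numeric vector of
#'   length 52 named by retained location id, degrees in \eqn{[0, 360)}.
#' @return a [VFGrid-class].
#' @examples
#' g <- buildGrid()
#' length(retainedIds(g))  # 52
#' @export
buildGrid <- function(adjacencyRule = c("queen", "rook"), gh_angle = NULL) {
  adjacencyRule <- match.arg(adjacencyRule)
  loc <- .grid242_layout()
  loc$gh_angle <- NA_real_
  keep <- !loc$is_blind_spot
  if (is.null(gh_angle)) {
    loc$gh_angle[keep] <- .gh_entry_angle(loc$x[keep], loc$y[keep])
  } else {
    if (length(gh_angle) != 52L || is.null(names(gh_angle))) {
      stop("gh_angle must be a length-52 vector named by retained location id",
           call. = FALSE)
    }
    idx <- match(loc$location_id[keep], as.integer(names(gh_angle)))
    if (anyNA(idx)) stop("gh_angle names must cover all retained locations",
                         call. = FALSE)
    loc$gh_angle[keep] <- as.numeric(gh_angle)[idx] %% 360
  }

  ret <- loc[keep, ]
  d2 <- outer(ret$x, ret$x, "-")^2 + outer(ret$y, ret$y, "-")^2
  lim <- if (adjacencyRule == "queen") 72 else 36   # (6*sqrt(2))^2, 6^2
  adj <- which(d2 > 0 & d2 <= lim + 1e-9, arr.ind = TRUE)
  adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
  pairs <- cbind(ret$location_id[adj[, 1]], ret$location_id[adj[, 2]])
  storage.mode(pairs) <- "integer"
  colnames(pairs) <- c("i", "j")

  z <- .compute_z_raw(loc, pairs)
  grid <- new("VFGrid", locations = loc, pairs = pairs,
              z = z, rule = adjacencyRule)
  if (!.grid_connected(grid)) {
    stop("retained-location adjacency graph is not connected", call. = FALSE)
  }
  validObject(grid)
  grid
}

.circ_diff <- function(d) pmin(d, 360 - d)

.compute_z_raw <- function(loc, pairs) {
  ang <- stats::setNames(loc$gh_angle, loc$location_id)
  a1 <- ang[as.character(pairs[, 1])]
  a2 <- ang[as.character(pairs[, 2])]
  raw <- .circ_diff(abs(a1 - a2) %% 360)
  m <- max(raw)
  if (m <= 0) stop("all adjacent entry angles identical; cannot normalise",
                   call. = FALSE)
  unname(raw / m)
}

.grid_connected <- function(grid) {
  ids <- retainedIds(grid)
  idx <- stats::setNames(seq_along(ids), ids)
  nb <- vector("list", length(ids))
  for (k in seq_len(nrow(grid@pairs))) {
    i <- idx[[as.character(grid@pairs[k, 1])]]
    j <- idx[[as.character(grid@pairs[k, 2])]]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  seen <- logical(length(ids))
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    cur <- stack[[1L]]
    stack <- stack[-1L]
    for (j in nb[[cur]]) if (!seen[j]) { seen[j] <- TRUE; stack <- c(stack, j) }
  }
  all(seen)
}

#' Anatomical dissimilarity of adjacent grid pairs
#'
#' Returns, for each adjacent pair \eqn{(i, j)} of retained locations, the
#' dissimilarity \eqn{z_{ij} = \mathrm{circ}(|\theta_i - \theta_j|) / \max},
#' where \eqn{\theta} is the optic-disc entry angle,
#' \eqn{\mathrm{circ}(d) = \min(d, 360 - d)} is the circular difference, and
#' the maximum is taken over all adjacent pairs of the grid so that
#' \eqn{z \in [0, 1]} with grid maximum exactly 1. Pairs whose nerve-fibre
#' bundles enter the disc at similar angles are anatomically correlated and
#' get small \eqn{z}; boundary-crossing pairs get large \eqn{z}.
#'
#' @param grid a [VFGrid-class].
#' @return data.frame with columns \code{i}, \code{j}, \code{z}.
#' @export
setMethod("pairDissimilarity", "VFGrid", function(grid) {
  data.frame(i = grid@pairs[, 1], j = grid@pairs[, 2], z = grid@z)
})
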