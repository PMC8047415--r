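#' Synthetic tissue geometries
#'
#' Desk-scale surrogates for atrial tissue: 1D strands and 2D rectangular
#' sheets of nodes with spacing `h` (mm). Electrical properties live on the
#' elements (segments between nodes in 1D, quadrilateral cells in 2D): an
#' integer label (`working`, `fibrotic_remodeled`, `nonconductive`), a
#' conductivity in S/m, optional named regions (e.g. `"LAW"`/`"RAW"` halves of
#' a two-chamber surrogate), and a segment id used for spatial aggregation of
#' vulnerability results. Nodes are placed at `(i-1)*h`, origin at the domain
#' corner; all coordinates are in mm.
#'
#' @param nx,ny node counts per axis (at least 3).
#' @param h node spacing in mm.
#' @param sigma baseline conductivity of working myocardium in S/m.
#' @param regions `"none"` for a homogeneous sheet, or `"law_raw"` to tag the
#'   left and right element halves as named regions `"LAW"` and `"RAW"`
#'   (a two-chamber surrogate used by the fibrosis presets).
#' @return An object of class `tissue_geometry`.
#' @examples
#' g <- make_sheet(100, 100, 0.5)
#' dim_mm(g)
#' @export
make_sheet <- function(nx, ny, h, sigma = 0.15,
                       regions = c("none", "law_raw")) {
  regions <- match.arg(regions)
  if (nx < 3 || ny < 3) .stopf("nx and ny must be >= 3 (got %s, %s)", nx, ny)
  if (h <= 0) .stopf("node spacing h must be positive")
  if (sigma < 0) .stopf("conductivity must be non-negative")
  enx <- nx - 1L
  eny <- ny - 1L
  geom <- structure(list(
    kind = "sheet", nx = as.integer(nx), ny = as.integer(ny), h = h,
    label = matrix(.LAB_WORKING, enx, eny),
    sigma = matrix(sigma, enx, eny),
    anisotropy = 1,
    regions = list(),
    segments = matrix(1L, enx, eny)
  ), class = "tissue_geometry")
  if (regions == "law_raw") {
    idx <- matrix(seq_len(enx * eny), enx, eny)
    half <- enx %/% 2
    geom$regions <- list(
      LAW = as.integer(idx[seq_len(half), ]),
      RAW = as.integer(idx[(half + 1L):enx, ])
    )
  }
  geom
}

#' @rdname make_sheet
#' @export
make_strand <- function(nx, h, sigma = 0.15) {
  if (nx < 3) .stopf("nx must be >= 3 (got %s)", nx)
  if (h <= 0) .stopf("node spacing h must be positive")
  if (sigma < 0) .stopf("conductivity must be non-negative")
  structure(list(
    kind = "strand", nx = as.integer(nx), ny = 1L, h = h,
    label = matrix(.LAB_WORKING, nx - 1L, 1L),
    sigma = matrix(sigma, nx - 1L, 1L),
    anisotropy = 1,
    regions = list(),
    segments = matrix(1L, nx - 1L, 1L)
  ), class = "tissue_geometry")
}

#' @export
print.tissue_geometry <- function(x, ...) {
  ext <- dim_mm(x)
  cat(sprintf("<tissue_geometry> %s, %d x %d nodes (h = %g mm, %g x %g mm)\n",
              x$kind, x$nx, x$ny, x$h, ext[1], ext[2]))
  tab <- table(factor(.label_names[x$label], levels = .label_names))
  cat("  elements:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n")
  if (length(x$regions))
    cat("  regions:", paste(names(x$regions), collapse = ", "), "\n")
  cat("  segments:", length(unique(as.vector(x$segments))), "\n")
  invisible(x)
}

#' Physical extent of a geometry in mm
#' @param geom a `tissue_geometry`.
#' @return numeric c(x extent, y extent), `(n - 1) * h` per axis.
#' @export
dim_mm <- function(geom) {
  c((geom$nx - 1L) * geom$h, (geom$ny - 1L) * geom$h)
}

.n_nodes <- function(geom) geom$nx * geom$ny

.n_elements <- function(geom) length(geom$label)

# node coordinates (mm), nodes ordered x-fastest
.node_xy <- function(geom) {
  cbind(x = rep.int((seq_len(geom$nx) - 1) * geom$h, geom$ny),
        y = rep((seq_len(geom$ny) - 1) * geom$h, each = geom$nx))
}

# logical per node: adjacent to at least one conductive element
.conductive_nodes <- function(geom) {
  cond_el <- geom$label != .LAB_NONCOND
  if (geom$kind == "strand") {
    ok <- logical(geom$nx)
    ok[seq_len(geom$nx - 1L)] <- cond_el[, 1]
    ok[2:geom$nx] <- ok[2:geom$nx] | cond_el[, 1]
    return(ok)
  }
  enx <- geom$nx - 1L
  eny <- geom$ny - 1L
  ok <- matrix(FALSE, geom$nx, geom$ny)
  ok[seq_len(enx), seq_len(eny)] <- cond_el
  ok[2:geom$nx, seq_len(eny)] <- ok[2:geom$nx, seq_len(eny)] | cond_el
  ok[seq_len(enx), 2:geom$ny] <- ok[seq_len(enx), 2:geom$ny] | cond_el
  ok[2:geom$nx, 2:geom$ny] <- ok[2:geom$nx, 2:geom$ny] | cond_el
  as.vector(ok)
}

# nearest node index (1-based, x-fastest) to a position c(x, y) in mm
.nearest_node <- function(geom, pos) {
  i <- max(1L, min(geom$nx, round(pos[1] / geom$h) + 1L))
  j <- if (geom$ny > 1L)
    max(1L, min(geom$ny, round(pos[2] / geom$h) + 1L)) else 1L
  as.integer((j - 1L) * geom$nx + i)
}

.node_pos <- function(geom, node) {
  i <- (node - 1L) %% geom$nx
  j <- (node - 1L) %/% geom$nx
  cbind(x = i * geom$h, y = j * geom$h)
}

#' Fibrosis presets
#'
#' Named presets describing which fraction of each named region is relabeled
#' as fibrotic and, within the fibrotic set, which fraction is made
#' electrically non-conductive (percolation). The two built-in presets follow
#' clinical fibrosis staging of the left/right atrial walls: `"UII"` (19% of
#' LAW, 5% of RAW fibrotic) and `"UIV"` (39% of LAW, 11% of RAW). Half of the
#' fibrotic elements are non-conductive by default; the remainder keep
#' conducting but receive the cytokine-remodeled membrane phenotype in the
#' tissue solver.
#'
#' @param name `"UII"`, `"UIV"` or `"custom"`.
#' @param fractions named numeric vector, fraction fibrotic per region
#'   (required for `"custom"`).
#' @param nonconductive_fraction fraction of fibrotic elements set
#'   non-conductive; default 0.5.
#' @param seed integer seed for the element sampling (mandatory: placement is
#'   random but must be reproducible).
#' @return object of class `fibrosis_preset`.
#' @export
fibrosis_preset <- function(name = c("UII", "UIV", "custom"),
                            fractions = NULL,
                            nonconductive_fraction = 0.5, seed) {
  name <- match.arg(name)
  if (missing(seed)) .stopf("a seed is required for fibrosis placement")
  if (is.null(fractions)) {
    fractions <- switch(name,
      UII = c(LAW = 0.19, RAW = 0.05),
      UIV = c(LAW = 0.39, RAW = 0.11),
      custom = .stopf("custom preset requires explicit fractions"))
  }
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    .stopf("fractions must be a named vector (region name -> fraction)")
  if (any(fractions < 0 | fractions > 1))
    .stopf("fibrotic fractions must lie in [0, 1]")
  if (nonconductive_fraction < 0 || nonconductive_fraction > 1)
    .stopf("nonconductive_fraction must lie in [0, 1]")
  structure(list(name = name, fractions = fractions,
                 nonconductive_fraction = nonconductive_fraction,
                 seed = as.integer(seed)),
            class = "fibrosis_preset")
}

#' Apply a fibrosis preset to a geometry
#'
#' Within each named region, exactly `round(fraction * |region|)` elements are
#' selected uniformly at random (without replacement, deterministic given the
#' preset seed). Of those, exactly `round(nonconductive_fraction * count)`
#' are set non-conductive with conductivity `1e-7` S/m; the remainder are
#' labeled `fibrotic_remodeled`.
#'
#' @param geom a `tissue_geometry` whose `regions` contain every region named
#'   by the preset.
#' @param preset a [fibrosis_preset()].
#' @return the modified `tissue_geometry`.
#' @export
apply_fibrosis <- function(geom, preset) {
  stopifnot(inherits(geom, "tissue_geometry"),
            inherits(preset, "fibrosis_preset"))
  unknown <- setdiff(names(preset$fractions), names(geom$regions))
  if (length(unknown))
    .stopf("unknown region(s): %s", paste(unknown, collapse = ", "))
  .with_seed(preset$seed, {
    for (rn in names(preset$fractions)) {
      region <- geom$regions[[rn]]
      n_fib <- round(preset$fractions[[rn]] * length(region))
      if (n_fib == 0) next
      fib <- sample(region, n_fib)
      n_nc <- round(preset$nonconductive_fraction * n_fib)
      nc <- if (n_nc > 0) fib[seq_len(n_nc)] else integer(0)
      rem <- setdiff(fib, nc)
      geom$label[nc] <- .LAB_NONCOND
      geom$sigma[nc] <- .SIGMA_NONCOND
      geom$label[rem] <- .LAB_FIBROTIC
    }
  })
  geom
}

#' Pacing site grids
#'
#' Places stimulation sites on a regular grid with inter-point distance `d`
#' mm (default 10 mm), keeping an exclusion margin from the domain boundary.
#' Sites landing on non-conductive tissue are snapped to the nearest
#' conductive node within `d/2`, or dropped (with a message) if none exists.
#'
#' @param geom a `tissue_geometry`.
#' @param d inter-point distance, mm; must be at least `2 * h`.
#' @param margin exclusion margin from the boundary, mm (default `d / 2`).
#' @return object of class `pacing_site_set`: a data frame of site positions
#'   and node indices with attributes `d` and `margin`.
#' @export
make_pacing_sites <- function(geom, d = 10, margin = d / 2) {
  stopifnot(inherits(geom, "tissue_geometry"))
  if (d < 2 * geom$h)
    .stopf("inter-point distance d = %g mm is below 2h = %g mm", d, 2 * geom$h)
  ext <- dim_mm(geom)
  xs <- seq(margin, ext[1] - margin + 1e-9, by = d)
  ys <- if (geom$ny > 1L) seq(margin, ext[2] - margin + 1e-9, by = d) else 0
  if (!length(xs) || !length(ys))
    .stopf("margin %g mm leaves no room for pacing sites", margin)
  cand <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  cond <- .conductive_nodes(geom)
  xy <- .node_xy(geom)
  keep <- logical(nrow(cand))
  node <- integer(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    n <- .nearest_node(geom, c(cand$x[k], cand$y[k]))
    if (cond[n]) {
      node[k] <- n
      keep[k] <- TRUE
    } else {
      dd <- sqrt((xy[, 1] - cand$x[k])^2 + (xy[, 2] - cand$y[k])^2)
      dd[!cond] <- Inf
      m <- which.min(dd)
      if (dd[m] <= d / 2) {
        node[k] <- m
        keep[k] <- TRUE
      } else {
        message(sprintf(
          "pacing site (%g, %g) dropped: no conductive node within d/2",
          cand$x[k], cand$y[k]))
      }
    }
  }
  sites <- data.frame(x = xy[node[keep], 1], y = xy[node[keep], 2],
                      node = node[keep],
                      cx = cand$x[keep], cy = cand$y[keep])
  structure(sites, d = d, margin = margin, class = c("pacing_site_set",
                                                     "data.frame"))
}

#' Partition a geometry into rectangular segments
#'
#' Divides the element grid into `k x k` (sheets) or `k` (strands)
#' equal-area rectangular blocks. Segments partition the domain: every
#' element belongs to exactly one segment.
#'
#' @param geom a `tissue_geometry`.
#' @param k blocks per axis, at least 1.
#' @return the geometry with its `segments` field replaced.
#' @export
partition_segments <- function(geom, k) {
  stopifnot(inherits(geom, "tissue_geometry"))
  if (k < 1) .stopf("k must be >= 1")
  k <- as.integer(k)
  enx <- nrow(geom$label)
  eny <- ncol(geom$label)
  bx <- pmin(k, ceiling(seq_len(enx) / (enx / k)))
  if (geom$kind == "strand" || eny == 1L) {
    geom$segments <- matrix(bx, enx, eny)
  } else {
    by <- pmin(k, ceiling(seq_len(eny) / (eny / k)))
    geom$segments <- matrix(0L, enx, eny)
    for (j in seq_len(eny))
      geom$segments[, j] <- as.integer((by[j] - 1L) * k + bx)
  }
  geom
}

#' Geodesic distance through conductive tissue
#'
#' Shortest-path distance between two positions through the conductive node
#' graph (8-neighbour adjacency, Euclidean edge weights). On obstacle-free
#' convex domains this equals the straight-line distance up to one grid
#' diagonal.
#'
#' @param geom a `tissue_geometry`.
#' @param a,b positions `c(x, y)` in mm (or node indices if integers given as
#'   length-1 vectors with `attr` ignored); both must map to conductive nodes.
#' @return distance in mm; `Inf` (with a warning) if the endpoints are not
#'   connected through conductive tissue.
#' @export
geodesic_distance <- function(geom, a, b) {
  stopifnot(inherits(geom, "tissue_geometry"))
  cond <- .conductive_nodes(geom)
  na <- .nearest_node(geom, a)
  nb <- .nearest_node(geom, b)
  if (!cond[na] || !cond[nb])
    .stopf("endpoints must lie on conductive tissue")
  d <- .grid_dijkstra_cpp(geom$nx, geom$ny, geom$h,
                          as.vector(geom$label != .LAB_NONCOND),
                          na - 1L)[nb]
  if (!is.finite(d))
    warning("endpoints are not connected through conductive tissue",
            call. = FALSE)
  d
}

# full geodesic distance map (mm) from a node, Inf where unreachable
.geodesic_map <- function(geom, node) {
  cond <- .conductive_nodes(geom)
  if (!cond[node]) .stopf("source node is not conductive")
  .grid_dijkstra_cpp(geom$nx, geom$ny, geom$h,
                     as.vector(geom$label != .LAB_NONCOND), node - 1L)
}
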