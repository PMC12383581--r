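#' Mesh sizing controls
#'
#' Sizing for the graded tetrahedral mesh: a global element size, a sphere
#' of influence centred at the tumour with a finer interior size, and a
#' finer size again in a small window around the device tip face.
#' Sizes are targets per grid direction of the tensor-product mesher.
#'
#' @param global_size target element size away from the tumour (mm).
#' @param influence_radius radius of the sphere of influence centred at
#'   the tumour centre (mm).
#' @param influence_size target size inside the sphere of influence (mm).
#' @param tip_face_size target size in the refinement window around the
#'   tip application face (mm).
#' @param influence_centre optional centre override (mm, length 3);
#'   defaults to the tumour centre of the model being meshed.
#' @return an object of class `cusa_sizing`.
#' @export
mesh_sizing <- function(global_size = 4.5, influence_radius = 20,
                        influence_size = 1.6, tip_face_size = 0.4,
                        influence_centre = NULL) {
  stopifnot(global_size > 0, influence_radius > 0,
            influence_size > 0, tip_face_size > 0)
  if (!(tip_face_size <= influence_size && influence_size <= global_size))
    stop("sizing contradiction: need tip_face_size <= influence_size <= global_size")
  structure(list(global_size = global_size,
                 influence_radius = influence_radius,
                 influence_size = influence_size,
                 tip_face_size = tip_face_size,
                 influence_centre = influence_centre),
            class = "cusa_sizing")
}

# --- 1D grading --------------------------------------------------------------

# subdivide [breaks] with target size per interval; breakpoints are kept
grade_intervals <- function(breaks, sizes) {
  out <- breaks[1]
  for (i in seq_along(sizes)) {
    len <- breaks[i + 1] - breaks[i]
    n <- max(1L, ceiling(len / sizes[i] - 1e-9))
    out <- c(out, breaks[i] + len * seq_len(n) / n)
  }
  out
}

dedup_sorted <- function(x, tol = 1e-9) x[c(TRUE, diff(x) > tol)]

# --- hex -> tet splitting ----------------------------------------------------

# corner column order: v000 v100 v010 v110 v001 v101 v011 v111
.tet_pattern_even <- rbind(c(1,2,3,5), c(4,3,2,8), c(6,2,5,8),
                           c(7,5,3,8), c(2,3,5,8))
.tet_pattern_odd  <- rbind(c(2,1,4,6), c(3,4,1,7), c(5,6,7,1),
                           c(8,7,6,4), c(1,4,6,7))

# split hex cells (rows of H, 8 corner node ids) into tets using the
# parity-alternating 5-tet decomposition; collapsed corners (repeated ids,
# e.g. wedges at the polar axis) yield degenerate tets that are dropped
split_hexes <- function(H, parity, cell_id = seq_len(nrow(H))) {
  tets <- NULL; owner <- NULL
  for (p in 0:1) {
    sel <- which(parity %% 2 == p)
    if (!length(sel)) next
    pat <- if (p == 0) .tet_pattern_even else .tet_pattern_odd
    for (r in seq_len(nrow(pat))) {
      tt <- H[sel, pat[r, ], drop = FALSE]
      tets <- rbind(tets, tt)
      owner <- c(owner, cell_id[sel])
    }
  }
  dup <- (tets[, 1] == tets[, 2]) | (tets[, 1] == tets[, 3]) |
    (tets[, 1] == tets[, 4]) | (tets[, 2] == tets[, 3]) |
    (tets[, 2] == tets[, 4]) | (tets[, 3] == tets[, 4])
  list(tets = tets[!dup, , drop = FALSE], owner = owner[!dup])
}

tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

orient_tets <- function(nodes, tets) {
  v <- tet_volumes(nodes, tets)
  flip <- v < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  tets
}

# --- face utilities ----------------------------------------------------------

.face_combs <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))

# all 4m oriented faces; face i of tet t is opposite vertex i and oriented
# outward from the tet
tet_faces <- function(tets) {
  m <- nrow(tets)
  f <- rbind(tets[, .face_combs[1, ]], tets[, .face_combs[2, ]],
             tets[, .face_combs[3, ]], tets[, .face_combs[4, ]])
  list(faces = f, tet = rep(seq_len(m), times = 4))
}

# fast row-sort for 3-column integer matrix
sort3 <- function(f) {
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
  cbind(lo, mid, hi)
}

face_key_fast <- function(f) {
  s <- sort3(f)
  (s[, 1] * 2^18 + s[, 2]) * 2^18 + s[, 3]
}

triangle_areas <- function(nodes, faces) {
  a <- nodes[faces[, 1], , drop = FALSE]
  u <- nodes[faces[, 2], , drop = FALSE] - a
  v <- nodes[faces[, 3], , drop = FALSE] - a
  nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(nx^2 + ny^2 + nz^2)
}

triangle_normals <- function(nodes, faces) {
  a <- nodes[faces[, 1], , drop = FALSE]
  u <- nodes[faces[, 2], , drop = FALSE] - a
  v <- nodes[faces[, 3], , drop = FALSE] - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n / sqrt(rowSums(n^2))
}

# classify all faces: returns boundary faces (outward oriented, with owner
# tet) and interior faces (with the two adjacent tets)
classify_faces <- function(tets) {
  tf <- tet_faces(tets)
  key <- face_key_fast(tf$faces)
  o <- order(key)
  k <- key[o]
  n <- length(k)
  same_prev <- c(FALSE, k[-1] == k[-n])
  same_next <- c(same_prev[-1], FALSE)
  cnt1 <- !same_prev & !same_next
  first_of_pair <- !same_prev & same_next
  if (any(same_prev & same_next))
    stop("meshing error: non-manifold face (shared by > 2 elements)")
  bidx <- o[cnt1]
  p1 <- o[first_of_pair]
  p2 <- o[which(first_of_pair) + 1]
  list(boundary_faces = tf$faces[bidx, , drop = FALSE],
       boundary_tet = tf$tet[bidx],
       pair_faces = tf$faces[p1, , drop = FALSE],
       pair_t1 = tf$tet[p1], pair_t2 = tf$tet[p2])
}

# --- exact circle/triangle intersection (2D) ---------------------------------

# signed area of disc(radius r, centred at origin) intersect triangle(O,A,B)
.disc_wedge_area <- function(ax, ay, bx, by, r) {
  cr <- ax * by - ay * bx
  if (abs(cr) < 1e-300) return(0)
  dx <- bx - ax; dy <- by - ay
  a2 <- dx^2 + dy^2
  b2 <- 2 * (ax * dx + ay * dy)
  c2 <- ax^2 + ay^2 - r^2
  disc <- b2^2 - 4 * a2 * c2
  ts <- numeric(0)
  if (disc > 0 && a2 > 0) {
    sq <- sqrt(disc)
    ts <- sort(c((-b2 - sq) / (2 * a2), (-b2 + sq) / (2 * a2)))
    ts <- ts[ts > 1e-12 & ts < 1 - 1e-12]
  }
  px <- c(ax, ax + ts * dx, bx)
  py <- c(ay, ay + ts * dy, by)
  tot <- 0
  for (i in seq_len(length(px) - 1)) {
    mx <- (px[i] + px[i + 1]) / 2; my <- (py[i] + py[i + 1]) / 2
    if (mx^2 + my^2 <= r^2) {
      tot <- tot + 0.5 * (px[i] * py[i + 1] - py[i] * px[i + 1])
    } else {
      th <- atan2(py[i + 1], px[i + 1]) - atan2(py[i], px[i])
      th <- th - 2 * pi * round(th / (2 * pi))
      tot <- tot + 0.5 * r^2 * th
    }
  }
  tot
}

# exact area of intersection of a polygon (vertex coords px, py) with a
# disc of radius r centred at the origin
circle_poly_area <- function(px, py, r) {
  n <- length(px)
  tot <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    tot <- tot + .disc_wedge_area(px[i], py[i], px[j], py[j], r)
  }
  abs(tot)
}

# --- box fixture mesh --------------------------------------------------------

#' Structured tetrahedral mesh of a box
#'
#' Tensor-product grid split into tetrahedra with the parity-consistent
#' 5-tet decomposition.  Used for verification fixtures (unit cube, slab,
#' bar).  Boundary facet sets are named `xmin`, `xmax`, `ymin`, `ymax`,
#' `zmin`, `zmax`.
#'
#' @param x_lines,y_lines,z_lines sorted grid coordinates (mm).
#' @param region region tag for all elements.
#' @return a `cusa_mesh`.
#' @export
box_mesh <- function(x_lines, y_lines, z_lines, region = "solid") {
  nx <- length(x_lines); ny <- length(y_lines); nz <- length(z_lines)
  stopifnot(nx >= 2, ny >= 2, nz >= 2)
  nodes <- cbind(rep(x_lines, times = ny * nz),
                 rep(rep(y_lines, each = nx), times = nz),
                 rep(z_lines, each = nx * ny))
  nid <- function(i, j, k) i + nx * ((j - 1) + ny * (k - 1))
  ci <- rep(seq_len(nx - 1), times = (ny - 1) * (nz - 1))
  cj <- rep(rep(seq_len(ny - 1), each = nx - 1), times = nz - 1)
  ck <- rep(seq_len(nz - 1), each = (nx - 1) * (ny - 1))
  H <- cbind(nid(ci, cj, ck),     nid(ci + 1, cj, ck),
             nid(ci, cj + 1, ck), nid(ci + 1, cj + 1, ck),
             nid(ci, cj, ck + 1), nid(ci + 1, cj, ck + 1),
             nid(ci, cj + 1, ck + 1), nid(ci + 1, cj + 1, ck + 1))
  sp <- split_hexes(H, (ci + cj + ck))
  tets <- orient_tets(nodes, sp$tets)
  cf <- classify_faces(tets)
  bf <- cf$boundary_faces
  cen <- (nodes[bf[, 1], , drop = FALSE] + nodes[bf[, 2], , drop = FALSE] +
          nodes[bf[, 3], , drop = FALSE]) / 3
  tol <- 1e-9
  sets <- list()
  planes <- list(xmin = c(1, x_lines[1]), xmax = c(1, x_lines[nx]),
                 ymin = c(2, y_lines[1]), ymax = c(2, y_lines[ny]),
                 zmin = c(3, z_lines[1]), zmax = c(3, z_lines[nz]))
  for (nm in names(planes)) {
    ax <- planes[[nm]][1]; val <- planes[[nm]][2]
    sel <- abs(cen[, ax] - val) < tol
    sets[[nm]] <- list(faces = bf[sel, , drop = FALSE],
                       owner = cf$boundary_tet[sel])
  }
  sets$boundary <- list(faces = bf, owner = cf$boundary_tet)
  structure(list(nodes = nodes, tets = tets,
                 region = rep(region, nrow(tets)),
                 sets = sets, model = NULL, sizing = NULL,
                 alpha = 1, node_theta = NULL),
            class = "cusa_mesh")
}

# --- main mesher -------------------------------------------------------------

#' Generate the graded tetrahedral mesh of a labelled solid model
#'
#' Meshes the layered model with a structured polar (r, theta, z)
#' tensor-product grid: grid surfaces coincide exactly with every tissue
#' interface, the azimuthal polygon radii are rescaled so each layer keeps
#' its exact cross-sectional area, and hexahedral cells are split into
#' tetrahedra with a parity-consistent 5-tet decomposition (collapsed to
#' 3-tet wedges on the axis).  Refinement follows the sizing's sphere of
#' influence and tip-face window.  Named facet sets are attached for the
#' tip application face (with exact circular clipping of the 2 mm disc in
#' the developed surface plane), the fixed supports (outer vertebrae) and
#' the convection boundary (all exterior facets).
#'
#' @param model a `cusa_model`.
#' @param sizing a `cusa_sizing`.
#' @return an object of class `cusa_mesh` with fields `nodes` (mm),
#'   `tets`, `region` (tag per element), `sets` (named facet sets),
#'   `tip_nodes` (node ids inside the tip disc), `alpha` (equal-area
#'   radius correction), `model`, `sizing`.
#' @export
generate_mesh <- function(model, sizing = mesh_sizing()) {
  g <- model$geometry
  r_t <- model$radii[["tumour"]]; r_fat <- model$radii[["fat"]]
  H <- g$total_height
  zc <- model$tumour_centre[3]
  tipr <- model$tip_radius

  # ---- theta grid (even count; fine window around the dorsal tip line)
  wth <- (tipr + 0.5) / r_t
  dth_tip <- sizing$tip_face_size / r_t
  dth_base <- sizing$influence_size / r_fat
  th_fine <- grade_intervals(c(pi / 2 - wth, pi / 2, pi / 2 + wth),
                             rep(min(dth_tip, dth_base), 2))
  th_coarse <- grade_intervals(c(pi / 2 + wth, pi / 2 - wth + 2 * pi),
                               dth_base)
  th <- c(th_fine, th_coarse[-c(1, length(th_coarse))])
  th <- sort(th %% (2 * pi))
  th <- dedup_sorted(th, tol = 1e-9)
  if (length(th) %% 2 == 1) { # parity consistency across the wrap
    i <- which.max(diff(th))
    th <- sort(c(th, (th[i] + th[i + 1]) / 2))
  }
  nth <- length(th)
  dtheta <- diff(c(th, th[1] + 2 * pi))
  alpha <- sqrt(sum(dtheta) / sum(sin(dtheta)))  # equal-area correction

  # ---- radial lines (positive; axis handled by wedges)
  fine_r <- min(sizing$influence_size, 2 * sizing$tip_face_size)
  rl <- grade_intervals(c(0, max(r_t - 1, r_t / 2), r_t),
                        c(sizing$influence_size, fine_r))[-1]
  rl <- c(rl, grade_intervals(c(r_t, model$radii[["cord"]]), fine_r)[-1])
  for (nm in c("csf", "dura", "fat")) {
    prev <- tail(rl, 1)
    rl <- c(rl, grade_intervals(c(prev, model$radii[[nm]]),
                                sizing$influence_size)[-1])
  }
  rl <- dedup_sorted(rl)
  n_core <- length(rl)
  nb <- max(1L, ceiling((model$arch_outer_radius - r_fat) /
                          sizing$global_size))
  bone_frac <- seq_len(nb) / nb
  NR <- n_core + nb
  layer_of_cell <- character(NR)
  mids <- (c(0, rl[-n_core]) + rl) / 2
  rad <- model$radii
  layer_of_cell[1:n_core] <-
    ifelse(mids <= rad[["tumour"]], "tumour_core",
    ifelse(mids <= rad[["cord"]], "spinal_cord",
    ifelse(mids <= rad[["csf"]], "csf",
    ifelse(mids <= rad[["dura"]], "dura_mater", "epidural_fat"))))
  layer_of_cell[(n_core + 1):NR] <- "bone"
  i_rt <- which(abs(rl - r_t) < 1e-9)  # ring index of the tumour surface

  # ---- z grid
  zb <- model$z_bands
  breaks <- sort(unique(c(0, H, zb$z0, zb$z1, model$tumour_z, zc,
                          max(0, zc - sizing$influence_radius),
                          min(H, zc + sizing$influence_radius),
                          max(0, zc - (tipr + 0.5)),
                          min(H, zc + (tipr + 0.5)))))
  breaks <- dedup_sorted(breaks)
  midz <- (breaks[-1] + breaks[-length(breaks)]) / 2
  zsize <- ifelse(abs(midz - zc) <= tipr + 0.5, sizing$tip_face_size,
           ifelse(abs(midz - zc) <= sizing$influence_radius,
                  sizing$influence_size, sizing$global_size))
  zl <- grade_intervals(breaks, zsize)
  zl <- dedup_sorted(zl)
  NZ <- length(zl)

  # ---- nodes: axis nodes first, then rings indexed (ir, itheta, iz)
  rout_th <- outer_radius(model, th)
  nid_ring <- function(ir, j, iz) NZ + ((iz - 1) * nth + (j - 1)) * NR + ir
  ring_r <- matrix(0, NR, nth)
  for (ir in seq_len(NR)) {
    ring_r[ir, ] <- if (ir <= n_core) alpha * rl[ir]
    else alpha * (r_fat + bone_frac[ir - n_core] * (rout_th - r_fat))
  }
  nn <- NZ + NR * nth * NZ
  nodes <- matrix(0, nn, 3)
  nodes[seq_len(NZ), 3] <- zl
  idx <- NZ + seq_len(NR * nth * NZ)
  ir_v <- rep(seq_len(NR), times = nth * NZ)
  j_v <- rep(rep(seq_len(nth), each = NR), times = NZ)
  iz_v <- rep(seq_len(NZ), each = NR * nth)
  rr <- ring_r[cbind(ir_v, j_v)]
  nodes[idx, 1] <- rr * cos(th[j_v])
  nodes[idx, 2] <- rr * sin(th[j_v])
  nodes[idx, 3] <- zl[iz_v]

  # ---- cells (radial cell 1 = axis wedges)
  cr <- rep(seq_len(NR), times = nth * (NZ - 1))
  cjj <- rep(rep(seq_len(nth), each = NR), times = NZ - 1)
  ckk <- rep(seq_len(NZ - 1), each = NR * nth)
  jp <- ifelse(cjj == nth, 1L, cjj + 1L)
  ax0 <- ckk; ax1 <- ckk + 1L
  v000 <- ifelse(cr == 1, ax0, nid_ring(cr - 1, cjj, ckk))
  v010 <- ifelse(cr == 1, ax0, nid_ring(cr - 1, jp, ckk))
  v001 <- ifelse(cr == 1, ax1, nid_ring(cr - 1, cjj, ckk + 1))
  v011 <- ifelse(cr == 1, ax1, nid_ring(cr - 1, jp, ckk + 1))
  Hx <- cbind(v000, nid_ring(cr, cjj, ckk), v010, nid_ring(cr, jp, ckk),
              v001, nid_ring(cr, cjj, ckk + 1), v011,
              nid_ring(cr, jp, ckk + 1))
  parity <- (cr + cjj + ckk)

  # ---- region tags per cell
  zmid <- (zl[ckk] + zl[ckk + 1]) / 2
  lay <- layer_of_cell[cr]
  regc <- lay
  in_tum_z <- zmid > model$tumour_z[1] & zmid < model$tumour_z[2]
  regc[lay == "tumour_core"] <-
    ifelse(in_tum_z[lay == "tumour_core"], "tumour", "spinal_cord")
  if (any(lay == "bone")) {
    bsel <- which(lay == "bone")
    bz <- zmid[bsel]
    tag <- character(length(bsel))
    for (b in seq_len(nrow(zb)))
      tag[bz > zb$z0[b] & bz < zb$z1[b]] <- zb$region[b]
    regc[bsel] <- tag
  }

  sp <- split_hexes(Hx, parity)
  tets <- orient_tets(nodes, sp$tets)
  region <- regc[sp$owner]
  vols <- tet_volumes(nodes, tets)
  if (any(vols <= 0))
    stop("meshing error: degenerate (non-positive volume) tetrahedron produced")

  # ---- facet sets
  cf <- classify_faces(tets)
  bf <- cf$boundary_faces
  sets <- list(convection = list(faces = bf, owner = cf$boundary_tet))
  vtags <- c("vertebra_1", paste0("vertebra_", g$n_vertebrae))
  fs <- region[cf$boundary_tet] %in% vtags
  if (!any(fs)) stop("meshing error: empty fixed_support facet set")
  sets$fixed_support <- list(faces = bf[fs, , drop = FALSE],
                             owner = cf$boundary_tet[fs])

  # tip application face: tumour/cord interface facets on the tumour
  # surface ring, clipped exactly against the tip disc in the developed
  # (arc-length, z) plane of the cylindrical surface
  pr <- region[cf$pair_t1]; ps <- region[cf$pair_t2]
  iface <- (pr == "tumour" & ps == "spinal_cord") |
    (ps == "tumour" & pr == "spinal_cord")
  pf <- cf$pair_faces[iface, , drop = FALSE]
  nrad <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
  on_ring <- abs(nrad - alpha * r_t) < 1e-6
  lat <- on_ring[pf[, 1]] & on_ring[pf[, 2]] & on_ring[pf[, 3]]
  pf <- pf[lat, , drop = FALSE]
  ntheta <- atan2(nodes[, 2], nodes[, 1])
  dev_s <- alpha * r_t * ((ntheta - pi / 2 + pi) %% (2 * pi) - pi)
  dev_w <- nodes[, 3] - zc
  # candidate selection by true 3-D distance from the tip centre (the
  # developed coordinates are discontinuous at the ventral seam)
  tipc <- c(0, alpha * r_t, zc)
  cen3 <- (nodes[pf[, 1], , drop = FALSE] + nodes[pf[, 2], , drop = FALSE] +
             nodes[pf[, 3], , drop = FALSE]) / 3
  d3 <- sqrt((cen3[, 1] - tipc[1])^2 + (cen3[, 2] - tipc[2])^2 +
               (cen3[, 3] - tipc[3])^2)
  cand <- which(d3 < tipr + 4 * sizing$tip_face_size + 2)
  clip <- numeric(length(cand)); devarea <- numeric(length(cand))
  max_span <- alpha * r_t * pi / 2   # seam-straddling guard
  for (q in seq_along(cand)) {
    f <- pf[cand[q], ]
    pxs <- dev_s[f]; pys <- dev_w[f]
    if (diff(range(pxs)) > max_span) next
    devarea[q] <- abs(pxs[1] * (pys[2] - pys[3]) + pxs[2] * (pys[3] - pys[1]) +
                        pxs[3] * (pys[1] - pys[2])) / 2
    clip[q] <- circle_poly_area(pxs, pys, tipr)
  }
  keep <- clip > 1e-12
  tip_faces <- pf[cand[keep], , drop = FALSE]
  if (!nrow(tip_faces)) stop("meshing error: empty tip_application_face set")
  sets$tip_application_face <- list(
    faces = tip_faces,
    clip_area = clip[keep], dev_area = devarea[keep],
    area = sum(clip[keep]))
  tip_nodes <- unique(as.vector(tip_faces))
  tip_nodes <- tip_nodes[sqrt(dev_s[tip_nodes]^2 + dev_w[tip_nodes]^2) <=
                           tipr + 1e-9]

  structure(list(nodes = nodes, tets = tets, region = region, sets = sets,
                 tip_nodes = tip_nodes, model = model, sizing = sizing,
                 alpha = alpha, node_theta = ntheta),
            class = "cusa_mesh")
}

#' @export
print.cusa_mesh <- function(x, ...) {
  cat("<cusa_mesh>", nrow(x$nodes), "nodes,", nrow(x$tets),
      "tetrahedra,", length(unique(x$region)), "regions\n")
  invisible(x)
}

# --- quality and surface extraction -----------------------------------------

#' Mesh quality report
#'
#' Per-element aspect ratio (longest edge over `2*sqrt(6)` times the
#' inradius; 1 for the regular tetrahedron), minimum dihedral angle, and
#' per-region volumes.  Elements whose minimum dihedral angle falls below
#' `sliver_dihedral` are flagged as slivers.
#'
#' @param mesh a `cusa_mesh`.
#' @param sliver_dihedral sliver threshold in degrees.
#' @return list with `n_elements`, `min_aspect`, `mean_aspect`,
#'   `max_aspect`, `min_dihedral_deg`, `n_slivers`, `region_volumes`
#'   (mm^3), `total_volume`.
#' @export
mesh_quality <- function(mesh, sliver_dihedral = 5) {
  if (is.null(mesh$tets) || nrow(mesh$tets) == 0) stop("empty mesh")
  nodes <- mesh$nodes; tets <- mesh$tets
  v <- abs(tet_volumes(nodes, tets))
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  el2 <- matrix(0, nrow(tets), 6)
  for (e in 1:6) {
    d <- nodes[tets[, edges[e, 1]], , drop = FALSE] -
      nodes[tets[, edges[e, 2]], , drop = FALSE]
    el2[, e] <- rowSums(d^2)
  }
  lmax <- sqrt(apply(el2, 1, max))
  # total face area -> inradius r = 3V / Atot
  atot <- 0
  nrm <- vector("list", 4)
  for (ff in 1:4) {
    fc <- tets[, .face_combs[ff, ], drop = FALSE]
    a <- nodes[fc[, 1], , drop = FALSE]
    u <- nodes[fc[, 2], , drop = FALSE] - a
    w <- nodes[fc[, 3], , drop = FALSE] - a
    nv <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    nrm[[ff]] <- nv / sqrt(rowSums(nv^2))
    atot <- atot + 0.5 * sqrt(rowSums(nv^2))
  }
  rin <- 3 * v / atot
  aspect <- lmax / (2 * sqrt(6) * rin)
  # dihedral between each pair of faces (outward normals n_i, n_j:
  # cos(dihedral) = -n_i . n_j)
  mind <- rep(pi, nrow(tets))
  for (i in 1:3) for (j in (i + 1):4) {
    cth <- -rowSums(nrm[[i]] * nrm[[j]])
    mind <- pmin(mind, acos(pmax(-1, pmin(1, cth))))
  }
  mind_deg <- mind * 180 / pi
  rv <- tapply(v, mesh$region, sum)
  list(n_elements = nrow(tets),
       min_aspect = min(aspect), mean_aspect = mean(aspect),
       max_aspect = max(aspect),
       min_dihedral_deg = min(mind_deg),
       n_slivers = sum(mind_deg < sliver_dihedral),
       region_volumes = rv[order(names(rv))],
       total_volume = sum(v))
}

#' Extract a named facet set or a region boundary surface
#'
#' @param mesh a `cusa_mesh`.
#' @param name a named facet set (`"tip_application_face"`,
#'   `"fixed_support"`, `"convection"`, or a box-face name for fixture
#'   meshes) or a region tag, in which case the boundary surface of that
#'   region (facets separating it from other regions or the exterior) is
#'   returned.
#' @return list with `faces`, `area` (mm^2; for the tip face the exact
#'   disc-clipped area) and per-facet `areas`.
#' @export
extract_surface <- function(mesh, name) {
  if (name %in% names(mesh$sets)) {
    s <- mesh$sets[[name]]
    if (!is.null(s$clip_area))
      return(list(faces = s$faces, areas = s$clip_area, area = s$area))
    ar <- triangle_areas(mesh$nodes, s$faces)
    return(list(faces = s$faces, areas = ar, area = sum(ar)))
  }
  if (name %in% mesh$region) {
    sub <- mesh$tets[mesh$region == name, , drop = FALSE]
    tf <- tet_faces(sub)
    key <- face_key_fast(tf$faces)
    tb <- table(key)
    once <- names(tb)[tb == 1]
    sel <- key %in% as.numeric(once)
    f <- tf$faces[sel, , drop = FALSE]
    ar <- triangle_areas(mesh$nodes, f)
    return(list(faces = f, areas = ar, area = sum(ar)))
  }
  stop(sprintf("lookup error: unknown surface or region '%s'", name))
}

# --- file formats ------------------------------------------------------------

#' Write a mesh in Gmsh MSH 4.1 ASCII format
#'
#' Nodes in one entity block; one 3-D entity block per region, with
#' physical names carrying the region tags.  Facet sets are not
#' serialized.
#' @param mesh a `cusa_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  regs <- sort(unique(mesh$region))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")
  w("$PhysicalNames", as.character(length(regs)))
  for (i in seq_along(regs)) w(sprintf('3 %d "%s"', i, regs[i]))
  w("$EndPhysicalNames")
  n <- nrow(mesh$nodes)
  w("$Entities", sprintf("0 0 0 %d", length(regs)))
  for (i in seq_along(regs))
    w(sprintf("%d -1e3 -1e3 -1e3 1e3 1e3 1e3 1 %d 0", i, i))
  w("$EndEntities")
  w("$Nodes", sprintf("1 %d 1 %d", n, n), sprintf("3 %d 0 %d", 1L, n))
  w(as.character(seq_len(n)))
  w(sprintf("%.17g %.17g %.17g",
            mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]))
  w("$EndNodes")
  m <- nrow(mesh$tets)
  w("$Elements", sprintf("%d %d 1 %d", length(regs), m, m))
  eid <- 1L
  for (i in seq_along(regs)) {
    sel <- which(mesh$region == regs[i])
    w(sprintf("3 %d 4 %d", i, length(sel)))
    tt <- mesh$tets[sel, , drop = FALSE]
    w(sprintf("%d %d %d %d %d", eid + seq_along(sel) - 1L,
              tt[, 1], tt[, 2], tt[, 3], tt[, 4]))
    eid <- eid + length(sel)
  }
  w("$EndElements")
  invisible(path)
}

#' Read a mesh written by [write_msh()]
#'
#' Restores nodes, tetrahedra and region tags (facet sets and model
#' metadata are not serialized in MSH).
#' @param path file path.
#' @return a `cusa_mesh`.
#' @export
read_msh <- function(path) {
  ln <- readLines(path)
  sec <- function(name) {
    i0 <- which(ln == paste0("$", name)) + 1L
    i1 <- which(ln == paste0("$End", name)) - 1L
    ln[i0:i1]
  }
  pn <- sec("PhysicalNames")
  nreg <- as.integer(pn[1])
  regs <- character(nreg)
  for (i in seq_len(nreg)) {
    m <- regmatches(pn[1 + i], regexec('^3 (\\d+) "(.*)"$', pn[1 + i]))[[1]]
    regs[as.integer(m[2])] <- m[3]
  }
  nd <- sec("Nodes")
  hdr <- as.integer(strsplit(nd[1], " ")[[1]])
  n <- hdr[2]
  coords <- nd[(2 + n + 1):(2 + n + n)]
  nodes <- do.call(rbind, lapply(strsplit(coords, " "), as.numeric))
  el <- sec("Elements")
  hdr <- as.integer(strsplit(el[1], " ")[[1]])
  tets <- NULL; region <- character(0)
  pos <- 2L
  while (pos <= length(el)) {
    bh <- as.integer(strsplit(el[pos], " ")[[1]])
    cnt <- bh[4]
    rows <- do.call(rbind, lapply(strsplit(el[pos + seq_len(cnt)], " "),
                                  as.integer))
    tets <- rbind(tets, rows[, 2:5, drop = FALSE])
    region <- c(region, rep(regs[bh[2]], cnt))
    pos <- pos + 1L + cnt
  }
  structure(list(nodes = nodes, tets = tets, region = region,
                 sets = list(), model = NULL, sizing = NULL, alpha = 1),
            class = "cusa_mesh")
}

#' Write a mesh with optional fields as VTK XML (VTU, ASCII)
#'
#' @param mesh a `cusa_mesh`.
#' @param path output path.
#' @param point_data named list of per-node numeric vectors.
#' @param cell_data named list of per-element numeric vectors; the region
#'   tag is always written as integer `region_id`.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  cell_data$region_id <- as.numeric(factor(mesh$region))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                   mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(as.character(4L * seq_len(m)), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("10", m), con)
  w('</DataArray></Cells>')
  if (length(point_data)) {
    w('<PointData>')
    for (nm in names(point_data)) {
      w('<DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(as.character(point_data[[nm]]), con)
      w('</DataArray>')
    }
    w('</PointData>')
  }
  w('<CellData>')
  for (nm in names(cell_data)) {
    w('<DataArray type="Float64" Name="%s" format="ascii">', nm)
    writeLines(as.character(cell_data[[nm]]), con)
    w('</DataArray>')
  }
  w('</CellData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}
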