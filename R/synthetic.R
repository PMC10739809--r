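# Seeded generator of toy multidomain fragment ensembles with known
# ground truth. Emulates two conformer pools of a three-domain protein -
# fragment AB (mobile domain A + shared domain B) and fragment BC
# (shared domain B + static domain C) - with rigid bead-cloud domains,
# flexible linkers, a planted hinge motion of A, a planted von Mises
# mixture for the B-C rotation dihedral, and a controllable fraction of
# A poses that collide with C upon recombination.

#' Specification of a synthetic fragment-ensemble pair
#'
#' Domains are rigid clouds of pseudo-C-alpha beads (0.38 nm lattice)
#' so that C-alpha-based analytics and uniform-bead scattering exercise
#' every pipeline stage without force fields. Domain A plays the mobile
#' recognition domain (N-SH2 analogue), B the shared middle domain
#' (C-SH2 analogue) and C the static catalytic domain (PTP analogue).
#'
#' @param seed integer master seed; the same seed reproduces the
#'   ensembles bead-for-bead.
#' @param n_members members per fragment ensemble, `c(ab =, bc =)`.
#' @param beads beads per domain, `c(A =, B =, C =)`.
#' @param radius optional effective domain radii (nm), `c(A =, B =, C =)`;
#'   default from the bead count at lattice density.
#' @param linker_len linker lengths in residues, `c(ab =, bc =)`.
#' @param linker_kappa circular concentration of the linker pivot
#'   dihedrals (larger = straighter linkers).
#' @param hinge_open_deg,hinge_open_sd_deg mean and spread (degrees) of
#'   the hinge angle placing A in open, clash-free poses.
#' @param hinge_closed_deg,hinge_closed_sd_deg mean and spread of the
#'   closed poses that fold A back onto C's position.
#' @param clash_fraction fraction of AB members drawn in the closed pose
#'   (the knob controlling how many recombination pairs fail the clash
#'   filter).
#' @param extra_modes list of planted independent modes applied to A on
#'   top of the hinge; each `list(type = "rotation"|"translation",
#'   axis = c(x,y,z), sd = degrees or nm)`.
#' @param dihedral_means_deg,dihedral_weights,dihedral_kappa planted von
#'   Mises mixture of the B-C rotation dihedral (means in the measured
#'   dihedral convention, degrees). The default concentration (10, i.e.
#'   a circular spread of ~18 degrees) leaves the two rotation basins
#'   connected across a low saddle of a few kJ/mol, the regime of a
#'   facile interdomain roto-translation.
#' @param piston_sd_nm spread of the axial (screw) displacement of C
#'   along the interdomain axis, nm; together with the spin this makes
#'   the B-to-C motion a roto-translation while leaving the planted
#'   dihedral exact.
#' @param clash_cutoff cutoff (nm) at which ground-truth pair clash
#'   counts are tabulated; default 0.38 nm, the bead spacing - two
#'   residue-level beads closer than one bead diameter overlap sterically
#'   (the all-atom analogue would be ~0.2 nm between heavy atoms).
#' @param gt_pairs number of leading members per ensemble for which
#'   ground-truth pair clash counts are stored (brute force).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1,
                           n_members = c(ab = 150, bc = 150),
                           beads = c(A = 60, B = 50, C = 110),
                           radius = NULL,
                           linker_len = c(ab = 6, bc = 2),
                           linker_kappa = 20,
                           hinge_open_deg = 55, hinge_open_sd_deg = 15,
                           hinge_closed_deg = 170, hinge_closed_sd_deg = 8,
                           clash_fraction = 0.3,
                           extra_modes = list(),
                           dihedral_means_deg = c(-100, -30),
                           dihedral_weights = c(0.6, 0.4),
                           dihedral_kappa = 10,
                           piston_sd_nm = 0.3,
                           clash_cutoff = 0.38,
                           gt_pairs = 20) {
  if (!is_count(seed)) stopf("seed must be an integer")
  if (any(n_members < 1)) stopf("need at least one member per ensemble")
  if (any(beads < 4)) stopf("each domain needs at least 4 beads")
  if (any(linker_len < 1)) stopf("linkers need at least one residue")
  if (clash_fraction < 0 || clash_fraction > 1)
    stopf("clash_fraction must be in [0, 1]")
  if (length(dihedral_means_deg) != length(dihedral_weights))
    stopf("dihedral means and weights differ in length")
  spec <- list(seed = as.integer(seed), n_members = n_members, beads = beads,
               radius = radius, linker_len = linker_len,
               linker_kappa = linker_kappa,
               hinge_open_deg = hinge_open_deg,
               hinge_open_sd_deg = hinge_open_sd_deg,
               hinge_closed_deg = hinge_closed_deg,
               hinge_closed_sd_deg = hinge_closed_sd_deg,
               clash_fraction = clash_fraction, extra_modes = extra_modes,
               dihedral_means_deg = dihedral_means_deg,
               dihedral_weights = dihedral_weights / sum(dihedral_weights),
               dihedral_kappa = dihedral_kappa, piston_sd_nm = piston_sd_nm,
               clash_cutoff = clash_cutoff, gt_pairs = gt_pairs)
  class(spec) <- "synthetic_spec"
  spec
}

BEAD_SPACING <- 0.38  # nm, pseudo-C-alpha

# Compact bead cloud: cubic-lattice points inside a sphere, innermost
# first (deterministic), recentred to zero mean.
lattice_cloud <- function(n, spacing = BEAD_SPACING) {
  m <- ceiling((n * 3 / (4 * pi))^(1 / 3)) + 2
  g <- as.matrix(expand.grid(-m:m, -m:m, -m:m)) * spacing
  r2 <- rowSums(g^2)
  ord <- order(r2, g[, 1], g[, 2], g[, 3])
  pts <- g[ord[seq_len(n)], , drop = FALSE]
  sweep(pts, 2, colMeans(pts))
}

domain_radius <- function(n, spacing = BEAD_SPACING) {
  (3 * n * spacing^3 / (4 * pi))^(1 / 3)
}

# Canonical frame layout shared by both fragment pools. B sits at the
# origin; C hangs below along -z; A attaches above at +z and swings about
# the x axis through the B-A anchor. Four marker beads (off-axis in B and
# C, on-axis in each) realise the interdomain rotation dihedral exactly.
synthetic_layout <- function(spec) {
  nb <- spec$beads
  r <- spec$radius %||% c(A = domain_radius(nb["A"]),
                          B = domain_radius(nb["B"]),
                          C = domain_radius(nb["C"]))
  names(r) <- c("A", "B", "C")
  l_ab <- (spec$linker_len[["ab"]] + 1) * BEAD_SPACING
  l_bc <- (spec$linker_len[["bc"]] + 1) * BEAD_SPACING
  cA <- c(0, 0, r[["B"]] + l_ab + r[["A"]])
  cC <- c(0, 0, -(r[["B"]] + l_bc + r[["C"]]))
  # residue numbering: A | linker ab | B | linker bc | C (contiguous)
  nA <- nb[["A"]]; nB <- nb[["B"]]; nC <- nb[["C"]]
  resA <- seq_len(nA)
  resLab <- nA + seq_len(spec$linker_len[["ab"]])
  resB <- nA + spec$linker_len[["ab"]] + seq_len(nB)
  resLbc <- max(resB) + seq_len(spec$linker_len[["bc"]])
  resC <- max(resLbc) + seq_len(nC)
  list(
    r = r, cA = cA, cC = cC,
    anchor_top = c(0, 0, r[["B"]]), anchor_bot = c(0, 0, -r[["B"]]),
    A_attach_local = c(0, 0, -r[["A"]]),
    # markers: p1 off-axis in B, p2 on-axis in B, p3 on-axis in C,
    # p4 off-axis in C (azimuth 0 at dihedral plant 0)
    markB = rbind(c(0.6 * r[["B"]], 0, 0.3 * r[["B"]]),
                  c(0, 0, -0.5 * r[["B"]])),
    markC = rbind(cC + c(0, 0, 0.5 * r[["C"]]),
                  cC + c(0.6 * r[["C"]], 0, 0.2 * r[["C"]])),
    cloudA = lattice_cloud(nA),
    cloudB = lattice_cloud(nB - 2),
    cloudC = lattice_cloud(nC - 2),
    res = list(A = resA, lab = resLab, B = resB, lbc = resLbc, C = resC),
    junction = resB[1] + floor(nB / 2),
    dihedral_resnos = c(resB[1], resB[2], resC[1], resC[2])
  )
}

bead_atoms <- function(resnos) {
  data.frame(name = "CA", element = "C", resno = resnos, resid = "ALA",
             chain = "A", stringsAsFactors = FALSE)
}

# B domain coordinates in the canonical frame: two markers then lattice.
b_coords <- function(lay) rbind(lay$markB, lay$cloudB)

# C domain in the canonical frame: spun by delta (radians) about the
# interdomain z axis and screwed along it by dz (nm). The axial shift
# leaves the marker azimuths - hence the planted dihedral - untouched.
c_coords <- function(lay, delta, dz = 0) {
  Rz <- rotation_about_axis(c(0, 0, 1), delta)
  cc <- rbind(lay$markC, sweep(lay$cloudC, 2, lay$cC, `+`))
  sweep(cc %*% t(Rz), 2, c(0, 0, -dz), `+`)
}

# A domain posed by hinge angle theta (radians, about x through the B-A
# anchor) plus extra planted modes; returns coordinates and attach point.
a_coords <- function(lay, theta, mode_amps, spec) {
  pose <- sweep(lay$cloudA, 2, lay$cA, `+`)
  att <- lay$cA + lay$A_attach_local
  Rh <- rotation_about_axis(c(1, 0, 0), theta)
  pv <- lay$anchor_top
  rot_about <- function(X, R) sweep(sweep(X, 2, pv) %*% t(R), 2, pv, `+`)
  pose <- rot_about(pose, Rh)
  att <- as.numeric(rot_about(rbind(att), Rh))
  for (k in seq_along(spec$extra_modes)) {
    md <- spec$extra_modes[[k]]
    if (md$type == "rotation") {
      R <- rotation_about_axis(md$axis, mode_amps[k] * pi / 180)
      pose <- rot_about(pose, R)
      att <- as.numeric(rot_about(rbind(att), R))
    } else {
      u <- md$axis / sqrt(sum(md$axis^2))
      pose <- sweep(pose, 2, u * mode_amps[k], `+`)
      att <- att + u * mode_amps[k]
    }
  }
  list(pose = pose, attach = att)
}

# Linker beads between two anchor points with seeded perpendicular
# jitter; redrawn if a bead falls into a domain cloud.
linker_beads <- function(from, to, n, kappa, avoid) {
  if (n < 1) return(matrix(numeric(0), 0, 3))
  dirv <- to - from
  len <- sqrt(sum(dirv^2))
  u <- dirv / len
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  t_frac <- seq_len(n) / (n + 1)
  base <- outer(t_frac, dirv) + matrix(from, n, 3, byrow = TRUE)
  amp <- BEAD_SPACING / sqrt(max(kappa, 1e-6))
  for (try in 1:10) {
    jit <- outer(stats::rnorm(n, 0, amp), e1) +
      outer(stats::rnorm(n, 0, amp), e2)
    beads <- base + jit
    if (!nrow(avoid)) break
    dmin <- min(sqrt(outer(rowSums(beads^2), rowSums(avoid^2), `+`) -
                       2 * tcrossprod(beads, avoid)))
    if (is.na(dmin) || dmin > 0.15) break
    if (try == 10) beads <- base
  }
  beads
}

#' Generate the two synthetic fragment ensembles with ground truth
#'
#' Draws `n_members` conformers for fragment AB (hinge-posed domain A +
#' shared domain B) and for fragment BC (shared domain B + spun domain
#' C), gives every member a random global rigid motion (which downstream
#' superpositions must remove), and records the ground truth each
#' pipeline stage is meant to recover.
#'
#' @param spec a [synthetic_spec()].
#' @return List: `ab`, `bc` ([ensemble3d()]s) and `ground_truth` with
#'   elements `domains` (residue-range [domain_def()]s), `junction`,
#'   `dihedral_resnos`, per-member `hinge_deg`, `mode_amps`,
#'   `dihedral_deg` (planted, measured convention), `com_A`, `rg_ab`,
#'   `rg_bc`, and `clash` (brute-force pair clash counts for the leading
#'   `gt_pairs` members at `clash_cutoff`).
#' @export
generate_fragment_ensembles <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  lay <- synthetic_layout(spec)
  res <- lay$res
  nm <- spec$n_members

  # --- fragment AB -------------------------------------------------------
  n_modes <- length(spec$extra_modes)
  closed <- stats::runif(nm[["ab"]]) < spec$clash_fraction
  theta_deg <- ifelse(closed,
                      stats::rnorm(nm[["ab"]], spec$hinge_closed_deg,
                                   spec$hinge_closed_sd_deg),
                      stats::rnorm(nm[["ab"]], spec$hinge_open_deg,
                                   spec$hinge_open_sd_deg))
  mode_amps <- matrix(0, nm[["ab"]], max(n_modes, 1))
  for (k in seq_len(n_modes))
    mode_amps[, k] <- stats::rnorm(nm[["ab"]], 0, spec$extra_modes[[k]]$sd)

  atoms_ab <- bead_atoms(c(res$A, res$lab, res$B))
  bxyz <- b_coords(lay)
  ab_members <- vector("list", nm[["ab"]])
  ab_canonical_A <- vector("list", nm[["ab"]])
  com_A <- matrix(0, nm[["ab"]], 3)
  rg_ab <- numeric(nm[["ab"]])
  for (i in seq_len(nm[["ab"]])) {
    ap <- a_coords(lay, theta_deg[i] * pi / 180, mode_amps[i, ], spec)
    lk <- linker_beads(lay$anchor_top, ap$attach, spec$linker_len[["ab"]],
                       spec$linker_kappa, rbind(ap$pose, bxyz))
    xyz <- rbind(ap$pose, lk, bxyz)
    ab_canonical_A[[i]] <- ap$pose
    # random global rigid motion (recorded implicitly; fits remove it)
    R <- random_rotation()
    tv <- stats::rnorm(3, 0, 1)
    xyz_w <- sweep(xyz %*% t(R), 2, tv, `+`)
    com_A[i, ] <- colMeans(xyz_w[seq_along(res$A), , drop = FALSE])
    cen <- sweep(xyz_w, 2, colMeans(xyz_w))
    rg_ab[i] <- sqrt(mean(rowSums(cen^2)))
    ab_members[[i]] <- structure3d(atoms_ab, xyz_w,
                                   source = sprintf("synthetic AB %d", i))
  }

  # --- fragment BC -------------------------------------------------------
  comp <- sample.int(length(spec$dihedral_weights), nm[["bc"]],
                     replace = TRUE, prob = spec$dihedral_weights)
  # markers are built so the measured dihedral equals minus the spin
  delta <- rvonmises(nm[["bc"]], 0, spec$dihedral_kappa) -
    spec$dihedral_means_deg[comp] * pi / 180
  dihedral_deg <- wrap_angle(-delta * 180 / pi)
  piston <- abs(stats::rnorm(nm[["bc"]], 0, spec$piston_sd_nm))

  atoms_bc <- bead_atoms(c(res$B, res$lbc, res$C))
  bc_members <- vector("list", nm[["bc"]])
  bc_canonical_C <- vector("list", nm[["bc"]])
  rg_bc <- numeric(nm[["bc"]])
  for (j in seq_len(nm[["bc"]])) {
    cxyz <- c_coords(lay, delta[j], piston[j])
    lk <- linker_beads(lay$anchor_bot, cxyz[1, ] + c(0, 0, 0.0),
                       spec$linker_len[["bc"]], spec$linker_kappa,
                       rbind(bxyz, cxyz))
    xyz <- rbind(bxyz, lk, cxyz)
    bc_canonical_C[[j]] <- cxyz
    R <- random_rotation()
    tv <- stats::rnorm(3, 0, 1)
    xyz_w <- sweep(xyz %*% t(R), 2, tv, `+`)
    cen <- sweep(xyz_w, 2, colMeans(xyz_w))
    rg_bc[j] <- sqrt(mean(rowSums(cen^2)))
    bc_members[[j]] <- structure3d(atoms_bc, xyz_w,
                                   source = sprintf("synthetic BC %d", j))
  }

  # --- ground-truth clash counts (brute force, canonical frames) ---------
  kA <- min(spec$gt_pairs, nm[["ab"]])
  kB <- min(spec$gt_pairs, nm[["bc"]])
  counts <- matrix(0L, kA, kB)
  cut2 <- spec$clash_cutoff^2
  for (i in seq_len(kA)) {
    A <- ab_canonical_A[[i]]
    a2 <- rowSums(A^2)
    for (j in seq_len(kB)) {
      Cc <- bc_canonical_C[[j]]
      d2 <- outer(a2, rowSums(Cc^2), `+`) - 2 * tcrossprod(A, Cc)
      counts[i, j] <- sum(d2 < cut2)
    }
  }

  domains <- list(
    A = domain_def("A", c(min(res$A), max(res$A))),
    B = domain_def("B", c(min(res$B), max(res$B))),
    C = domain_def("C", c(min(res$C), max(res$C))))

  list(ab = ensemble3d(ab_members), bc = ensemble3d(bc_members),
       ground_truth = list(
         domains = domains, junction = lay$junction,
         dihedral_resnos = lay$dihedral_resnos,
         hinge_deg = theta_deg, closed = closed, mode_amps = mode_amps,
         dihedral_deg = dihedral_deg, piston_nm = piston,
         dihedral_means_deg = spec$dihedral_means_deg,
         dihedral_weights = spec$dihedral_weights,
         com_A = com_A, rg_ab = rg_ab, rg_bc = rg_bc,
         clash = list(counts = counts, cutoff = spec$clash_cutoff),
         layout = lay))
}

#' Carve a full-length parent into its two overlapping fragments
#'
#' Builds one full-length A-B-C conformer (intermediate, clash-free
#' pose), carves the AB and BC fragments out of it, and hands each
#' fragment a distinct random rigid motion - the self-consistency fixture
#' for [assemble_full_length()]: recombining the fragments must reproduce
#' the parent.
#'
#' @param spec a [synthetic_spec()].
#' @return List: `parent`, `ab`, `bc` ([structure3d()]s), `junction`
#'   residue, `junction_bond` (the parent's own seam C-alpha distance,
#'   nm), `domains`.
#' @export
carve_parent <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  lay <- synthetic_layout(spec)
  res <- lay$res
  ap <- a_coords(lay, 90 * pi / 180, numeric(length(spec$extra_modes)), spec)
  lk_ab <- linker_beads(lay$anchor_top, ap$attach, spec$linker_len[["ab"]],
                        spec$linker_kappa, rbind(ap$pose, b_coords(lay)))
  cxyz <- c_coords(lay, -spec$dihedral_means_deg[1] * pi / 180)
  lk_bc <- linker_beads(lay$anchor_bot, cxyz[1, ], spec$linker_len[["bc"]],
                        spec$linker_kappa, rbind(b_coords(lay), cxyz))
  resnos <- c(res$A, res$lab, res$B, res$lbc, res$C)
  xyz <- rbind(ap$pose, lk_ab, b_coords(lay), lk_bc, cxyz)
  parent <- structure3d(bead_atoms(resnos), xyz, source = "synthetic parent")

  carve <- function(keep, label, move) {
    s <- structure3d(parent$atoms[keep, ], parent$xyz[keep, , drop = FALSE],
                     source = label)
    if (!move) return(s)
    tr <- list(rotation = random_rotation(), translation = stats::rnorm(3))
    class(tr) <- "rigid_transform"
    apply_transform(s, tr)
  }
  # AB is displaced by a random rigid motion (the superposition at the
  # shared domain must undo it); BC keeps the parent frame so the
  # reassembly can be compared to the parent coordinate-by-coordinate
  ab <- carve(parent$atoms$resno <= max(res$B), "carved AB", move = TRUE)
  bc <- carve(parent$atoms$resno >= min(res$B), "carved BC", move = FALSE)
  jb <- sqrt(sum((xyz[match(lay$junction - 1, resnos), ] -
                    xyz[match(lay$junction, resnos), ])^2))
  list(parent = parent, ab = ab, bc = bc, junction = lay$junction,
       junction_bond = jb,
       domains = list(A = domain_def("A", c(min(res$A), max(res$A))),
                      B = domain_def("B", c(min(res$B), max(res$B))),
                      C = domain_def("C", c(min(res$C), max(res$C)))))
}
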