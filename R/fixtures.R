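# Idealized side-chain atom offsets from CA, in the (u, w) frame where u is
# the outward radial direction of the helix at the residue and w lies along
# the helix axis. Coarse single-rotamer geometry: sufficient for
# hydrogen-bond placement tests, not for packing realism.
.SIDECHAIN_OFFSETS <- list(
  ALA = list(c("CB", 1.5, 0)),
  LEU = list(c("CB", 1.5, 0), c("CG", 2.9, 0.3), c("CD1", 4.2, 0.9),
             c("CD2", 4.2, -0.5)),
  SER = list(c("CB", 1.5, 0), c("OG", 2.9, 0)),
  THR = list(c("CB", 1.5, 0), c("OG1", 2.9, 0.35), c("CG2", 2.7, -1.0)),
  ASN = list(c("CB", 1.5, 0), c("CG", 2.9, 0), c("OD1", 4.0, 0.6),
             c("ND2", 4.0, -0.7)),
  ASP = list(c("CB", 1.5, 0), c("CG", 2.9, 0), c("OD1", 4.0, 0.6),
             c("OD2", 4.0, -0.7)),
  GLN = list(c("CB", 1.5, 0), c("CG", 2.9, 0), c("CD", 4.3, 0),
             c("OE1", 5.4, 0.6), c("NE2", 5.4, -0.7)),
  GLU = list(c("CB", 1.5, 0), c("CG", 2.9, 0), c("CD", 4.3, 0),
             c("OE1", 5.4, 0.6), c("OE2", 5.4, -0.7)),
  HIS = list(c("CB", 1.5, 0), c("CG", 2.9, 0), c("ND1", 3.9, 1.0),
             c("CD2", 3.9, -1.0), c("CE1", 5.2, 0.7), c("NE2", 5.2, -0.6)),
  TYR = list(c("CB", 1.5, 0), c("CG", 2.9, 0), c("CZ", 5.6, 0),
             c("OH", 7.0, 0)),
  GLY = list()
)

#' Helix-bundle fixture specification
#'
#' Defaults mirror a seven-transmembrane-helix receptor: helices 1-5
#' labelled `static`, helices 6-7 `switchable`. Per-helix sequences default
#' to leucine with serine at inward-facing positions (providing polar
#' side-chain anchors for water planting).
#'
#' @param n_helices number of helices (default 7).
#' @param bundle_radius radius of the circle of helix axes (A).
#' @param residues_per_helix residues per helix (default 14).
#' @param sequences optional character vector of per-helix 3-letter-code
#'   sequences (semicolon-separated codes) or `NULL` for the default.
#' @param class_labels per-helix `static`/`switchable`; default 1-5 static,
#'   last two switchable.
#' @return A `bundle_spec` list.
#' @export
bundle_spec <- function(n_helices = 7L, bundle_radius = 8.5,
                        residues_per_helix = 14L, sequences = NULL,
                        class_labels = NULL) {
  if (is.null(class_labels))
    class_labels <- c(rep("static", max(0L, n_helices - 2L)),
                      rep("switchable", min(2L, n_helices)))
  if (length(class_labels) != n_helices)
    stop("class_labels must cover all helices")
  structure(list(n_helices = n_helices, bundle_radius = bundle_radius,
                 residues_per_helix = residues_per_helix,
                 sequences = sequences, class_labels = class_labels),
            class = "bundle_spec")
}

#' Build an annotated synthetic helix bundle
#'
#' Ideal alpha-helices (1.5 A rise, 100 degree twist per residue) placed on
#' a circle, alternating up/down, with backbone N/CA/C/O atoms, CB, and
#' idealized polar side chains (see the offset table). The annotation uses
#' synthetic BW codes `helix.(40+index)` so downstream reporting works
#' unchanged; helices are classed per the spec (default: 1-5 static, 6-7
#' switchable). Deterministic for a given spec and seed.
#'
#' @param spec a [bundle_spec].
#' @param seed integer seed (controls the global azimuthal offset).
#' @return list with `model` ([structure_model]) and `annotation`
#'   (`bw_annotation`).
#' @export
make_bundle <- function(spec = bundle_spec(), seed = 1L) {
  set.seed(seed)
  global_rot <- stats::runif(1, 0, 2 * pi)
  n <- spec$n_helices; m <- spec$residues_per_helix; R <- spec$bundle_radius
  seqs <- spec$sequences
  rows <- list(); ann <- list()
  serial <- 0L
  for (k in seq_len(n)) {
    phi <- 2 * pi * (k - 1) / n + global_rot
    axis_xy <- c(R * cos(phi), R * sin(phi))
    dirz <- if (k %% 2 == 1) 1 else -1
    theta0 <- phi + pi  # residue 1 side chain faces the bundle core
    ca_at <- function(i) {
      th <- theta0 + dirz * (100 * pi / 180) * (i - 1)
      z <- dirz * (1.5 * (i - 1) - 1.5 * (m - 1) / 2)
      c(axis_xy + 2.3 * c(cos(th), sin(th)), z)
    }
    # default sequence: SER at inward-facing positions, LEU elsewhere
    if (is.null(seqs)) {
      inward <- -c(cos(phi), sin(phi))
      seq_k <- vapply(seq_len(m), function(i) {
        ca <- ca_at(i)
        u <- ca[1:2] - axis_xy; u <- u / sqrt(sum(u^2))
        if (sum(u * inward) > 0.6) "SER" else "LEU"
      }, character(1))
    } else {
      seq_k <- strsplit(seqs[k], ";", fixed = TRUE)[[1]]
      if (length(seq_k) != m) stop("sequence length mismatch for helix ", k)
    }
    for (i in seq_len(m)) {
      ca <- ca_at(i)
      ca_prev <- ca_at(i - 1); ca_next <- ca_at(i + 1)
      unit <- function(v) v / sqrt(sum(v^2))
      npos <- ca + 1.46 * unit(ca_prev - ca)
      cpos <- ca + 1.52 * unit(ca_next - ca)
      radial_at <- function(p) unit(c(p[1:2] - axis_xy, 0))
      u <- radial_at(ca)
      w <- c(0, 0, dirz)
      opos <- cpos + 1.23 * w  # helical carbonyl points along the axis
      resname <- seq_k[i]
      offs <- .SIDECHAIN_OFFSETS[[resname]]
      if (is.null(offs)) stop("unsupported fixture residue: ", resname)
      atoms <- list(N = npos, CA = ca, C = cpos, O = opos)
      for (o in offs)
        atoms[[o[1]]] <- ca + as.numeric(o[2]) * u + as.numeric(o[3]) * w
      resnum <- (k - 1L) * m + i
      for (an in names(atoms)) {
        serial <- serial + 1L
        rows[[serial]] <- data.frame(
          serial = serial, name = an, altloc = "", resname = resname,
          chain = "A", resnum = resnum, icode = "",
          x = atoms[[an]][1], y = atoms[[an]][2], z = atoms[[an]][3],
          occ = 1, bfac = 0, element = substr(an, 1, 1), record = "ATOM",
          stringsAsFactors = FALSE)
      }
      ann[[resnum]] <- data.frame(chain = "A", resnum = resnum,
                                  bw = sprintf("%d.%d", k, 40L + i),
                                  helix = k, class = spec$class_labels[k],
                                  stringsAsFactors = FALSE)
    }
  }
  model <- structure_model(do.call(rbind, rows),
                           model_id = sprintf("bundle_seed%d", seed))
  list(model = model, annotation = bw_annotation(do.call(rbind, ann)))
}

# Anchor table: one polar side-chain atom per residue (preferring
# acceptor-capable atoms so planted waters can always donate), with helix,
# class and antecedent coordinates.
.bundle_anchors <- function(model, annotation) {
  a <- model$atoms[model$atoms$kind == "polymer", , drop = FALSE]
  out <- list()
  for (rk in unique(paste(a$chain, a$resnum, sep = "|"))) {
    parts <- strsplit(rk, "|", fixed = TRUE)[[1]]
    res <- a[a$chain == parts[1] & a$resnum == as.integer(parts[2]), , drop = FALSE]
    tab <- suppressWarnings(polar_atom_table(res$resname[1]))
    sc <- tab[!(tab$name %in% c("N", "O", "OXT")), , drop = FALSE]
    if (!nrow(sc)) next
    pref <- order(!(sc$role %in% c("acceptor", "both")))  # acceptors first
    sc <- sc[pref, , drop = FALSE]
    hit <- match(sc$name, res$name)
    j <- which(!is.na(hit))[1]
    if (is.na(j)) next
    at <- res[hit[j], ]
    antec <- res[match(sc$antecedent[j], res$name), ]
    look <- bw_lookup(annotation, parts[1], as.integer(parts[2]))
    out[[length(out) + 1L]] <- data.frame(
      chain = parts[1], resnum = as.integer(parts[2]),
      name = at$name, donor_only = sc$role[j] == "donor",
      x = at$x, y = at$y, z = at$z,
      ax = antec$x, ay = antec$y, az = antec$z,
      helix = if (is.null(look)) NA_integer_ else look$helix,
      class = if (is.null(look)) "none" else look$class,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Geometric interference check for one candidate water position, written as
# direct distance arithmetic (independent of the bond-detection code).
# `intended` are coordinates the water is supposed to contact.
.water_ok <- function(w, intended, polar_xyz, heavy_xyz, placed_waters,
                      partner_water = NULL) {
  dpol <- sqrt(colSums((t(polar_xyz) - w)^2))
  for (p in intended) {
    d <- sqrt(sum((p - w)^2))
    if (d < 2.5 || d > 3.2) return(FALSE)
  }
  imatch <- vapply(seq_len(nrow(polar_xyz)), function(i)
    any(vapply(intended, function(p)
      sum(abs(polar_xyz[i, ] - p)) < 1e-6, logical(1))), logical(1))
  if (any(dpol[!imatch] <= 3.6)) return(FALSE)
  dheavy <- sqrt(colSums((t(heavy_xyz) - w)^2))
  if (any(dheavy < 2.0)) return(FALSE)
  if (length(placed_waters)) {
    for (pw in placed_waters) {
      d <- sqrt(sum((pw - w)^2))
      is_partner <- !is.null(partner_water) && sum(abs(pw - partner_water)) < 1e-6
      if (is_partner) {
        if (d < 2.5 || d > 3.2) return(FALSE)
      } else if (d <= 3.6) return(FALSE)
    }
  }
  TRUE
}

# angle feasibility for donor-only anchors: antecedent-anchor-water >= 95 deg
.anchor_angle_ok <- function(anchor, w) {
  if (!anchor$donor_only) return(TRUE)
  ang <- .angle_deg(c(anchor$ax, anchor$ay, anchor$az),
                    c(anchor$x, anchor$y, anchor$z), w)
  !is.na(ang) && ang >= 95
}

#' Plant a water-bridge network with known counts
#'
#' Places water oxygens forming the requested bridges between the named
#' residues' polar side-chain anchors: a `single` bridge is one water at
#' 2.8 A from both anchors; a `chain2` bridge is two waters, each 2.8 A
#' from its anchor and 2.8 A apart. Placement is verified by direct
#' distance arithmetic: intended contacts within the bond window,
#' unintended polar atoms and foreign waters kept beyond it, and
#' donor-only anchors given a feasible approach angle. The analytically
#' expected counts are returned as ground truth: each opposite-class
#' `single` bridge contributes 2 mediating edges and each opposite-class
#' `chain2` bridge 3.
#'
#' @param model bundle [structure_model].
#' @param annotation its `bw_annotation`.
#' @param bridges data.frame with columns `kind` (`single`/`chain2`),
#'   `resnum_a`, `resnum_b` (author numbers on chain A).
#' @return list with `model` (waters appended), `expected`
#'   (`n_water_mediated_total`, `n_static_switchable`) and `waters`
#'   (placed positions with bridge ids).
#' @export
plant_water_network <- function(model, annotation, bridges) {
  anchors <- .bundle_anchors(model, annotation)
  pa <- .polar_atoms(model)
  polar_xyz <- atom_xyz(pa)
  heavy <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  heavy_xyz <- atom_xyz(heavy)
  placed <- list(); placed_info <- list()
  n_total <- 0L; n_ss <- 0L
  for (b in seq_len(nrow(bridges))) {
    ra <- anchors[anchors$resnum == bridges$resnum_a[b], , drop = FALSE]
    rb <- anchors[anchors$resnum == bridges$resnum_b[b], , drop = FALSE]
    if (!nrow(ra) || !nrow(rb))
      stop("bridge ", b, ": residue has no polar side-chain anchor")
    pA <- c(ra$x, ra$y, ra$z); pB <- c(rb$x, rb$y, rb$z)
    D <- sqrt(sum((pA - pB)^2))
    e <- (pB - pA) / D
    # orthonormal pair perpendicular to e
    ref <- if (abs(e[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    n1 <- ref - sum(ref * e) * e; n1 <- n1 / sqrt(sum(n1^2))
    n2 <- c(e[2] * n1[3] - e[3] * n1[2], e[3] * n1[1] - e[1] * n1[3],
            e[1] * n1[2] - e[2] * n1[1])
    opposite <- (ra$class == "static" && rb$class == "switchable") ||
      (ra$class == "switchable" && rb$class == "static")
    success <- FALSE
    for (psi in seq(0, 2 * pi, length.out = 25L)[-25L]) {
      nv <- cos(psi) * n1 + sin(psi) * n2
      if (bridges$kind[b] == "single") {
        if (D >= 5.58 || D < 2.0) break
        h <- sqrt(max(0, 2.8^2 - (D / 2)^2))
        w <- (pA + pB) / 2 + h * nv
        if (.water_ok(w, list(pA, pB), polar_xyz, heavy_xyz, placed) &&
            .anchor_angle_ok(ra, w) && .anchor_angle_ok(rb, w)) {
          placed[[length(placed) + 1L]] <- w
          placed_info[[length(placed_info) + 1L]] <-
            data.frame(bridge = b, x = w[1], y = w[2], z = w[3])
          n_total <- n_total + 2L
          if (opposite) n_ss <- n_ss + 2L
          success <- TRUE
        }
      } else {
        cosq <- (D - 2.8) / 5.6
        if (cosq > 0.999 || cosq < -0.999) break
        sinq <- sqrt(1 - cosq^2)
        w1 <- pA + 2.8 * (cosq * e + sinq * nv)
        w2 <- pB + 2.8 * (-cosq * e + sinq * nv)
        ok1 <- .water_ok(w1, list(pA), polar_xyz, heavy_xyz,
                         c(placed, list(w2)), partner_water = w2)
        ok2 <- .water_ok(w2, list(pB), polar_xyz, heavy_xyz,
                         c(placed, list(w1)), partner_water = w1)
        if (ok1 && ok2 && .anchor_angle_ok(ra, w1) && .anchor_angle_ok(rb, w2)) {
          placed <- c(placed, list(w1, w2))
          placed_info[[length(placed_info) + 1L]] <-
            data.frame(bridge = b, x = c(w1[1], w2[1]), y = c(w1[2], w2[2]),
                       z = c(w1[3], w2[3]))
          n_total <- n_total + 3L
          if (opposite) n_ss <- n_ss + 3L
          success <- TRUE
        }
      }
      if (success) break
    }
    if (!success)
      stop("placement error: bridge ", b, " (", bridges$kind[b], ", residues ",
           bridges$resnum_a[b], "-", bridges$resnum_b[b],
           ") is geometrically infeasible")
  }
  a <- model$atoms
  winfo <- do.call(rbind, placed_info)
  if (!is.null(winfo)) {
    wdf <- data.frame(
      serial = max(a$serial) + seq_len(nrow(winfo)),
      name = "O", altloc = "", resname = "HOH", chain = "S",
      resnum = seq_len(nrow(winfo)), icode = "",
      x = winfo$x, y = winfo$y, z = winfo$z,
      occ = 1, bfac = 0, element = "O", record = "HETATM",
      kind = "water", stringsAsFactors = FALSE)
    a <- rbind(a, wdf[, names(a)])
  }
  out <- structure_model(a, model_id = paste0(model$model_id, "+waters"),
                         energy = model$energy, source = model$source)
  list(model = out,
       expected = list(n_water_mediated_total = n_total,
                       n_static_switchable = n_ss),
       waters = winfo)
}

#' Randomized planted-network fixture
#'
#' Builds a bundle, samples feasible static-switchable bridges (and
#' optionally same-class decoys that add water-mediated bonds without
#' adding static-switchable ones), and plants them. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param n_single number of single-water static-switchable bridges.
#' @param n_chain2 number of two-water chains.
#' @param n_decoy number of same-class single bridges (default 1).
#' @param spec a [bundle_spec].
#' @return As [plant_water_network], plus `annotation` and `bridges`.
#' @export
random_planted_fixture <- function(seed, n_single = 2L, n_chain2 = 1L,
                                   n_decoy = 1L, spec = bundle_spec()) {
  bd <- make_bundle(spec, seed = seed)
  anchors <- .bundle_anchors(bd$model, bd$annotation)
  set.seed(seed + 7919L)
  pair_cand <- function(classes_differ, dmin, dmax) {
    idx <- which(anchors$class %in% c("static", "switchable"))
    cand <- list()
    for (i in idx) for (j in idx) {
      if (i >= j) next
      differ <- anchors$class[i] != anchors$class[j]
      if (differ != classes_differ) next
      if (anchors$helix[i] == anchors$helix[j]) next
      D <- sqrt((anchors$x[i] - anchors$x[j])^2 +
                  (anchors$y[i] - anchors$y[j])^2 +
                  (anchors$z[i] - anchors$z[j])^2)
      if (D >= dmin && D <= dmax)
        cand[[length(cand) + 1L]] <- c(anchors$resnum[i], anchors$resnum[j])
    }
    if (length(cand)) cand[sample.int(length(cand))] else cand
  }
  singles <- pair_cand(TRUE, 4.2, 5.4)
  chains <- pair_cand(TRUE, 6.2, 8.2)
  decoys <- pair_cand(FALSE, 4.2, 5.4)
  used <- integer()
  bridges <- data.frame(kind = character(), resnum_a = integer(),
                        resnum_b = integer(), stringsAsFactors = FALSE)
  take <- function(cands, kind, want) {
    got <- 0L
    for (p in cands) {
      if (got >= want) break
      if (any(p %in% used)) next
      trial <- rbind(bridges, data.frame(kind = kind, resnum_a = p[1],
                                         resnum_b = p[2]))
      ok <- tryCatch({
        plant_water_network(bd$model, bd$annotation, trial); TRUE
      }, error = function(e) FALSE)
      if (ok) {
        bridges <<- trial
        used <<- c(used, p)
        got <- got + 1L
      }
    }
    got
  }
  if (take(singles, "single", n_single) < n_single ||
      take(chains, "chain2", n_chain2) < n_chain2 ||
      take(decoys, "single", n_decoy) < n_decoy)
    stop("could not find enough feasible bridges for seed ", seed)
  res <- plant_water_network(bd$model, bd$annotation, bridges)
  res$annotation <- bd$annotation
  res$bridges <- bridges
  res
}

#' Build a synthetic ion-binding-site model
#'
#' Places three aspartate-like carboxylate groups forming a coordination
#' cage with a well-defined energy minimum under the default scorer. The
#' global minimum is located at generation time by dense grid scans, the
#' cage is translated so that the minimum coincides with the requested
#' `center` (mirroring real input structures, where the grid is anchored at
#' the known ion position), and the result is re-verified. Generation fails
#' if the optimum is ambiguous (near-degenerate positions far apart).
#'
#' @param center 3-vector: requested location of the energy minimum, i.e.
#'   the known ion position of the synthetic site.
#' @param r_oxy radius of the carboxylate oxygens from the cage centre (A).
#' @param seed seed controlling the cage orientation.
#' @param config [scorer_config] used for verification.
#' @param verify_spacing dense-scan spacing for verification (A).
#' @return list with `model`, `true_minimum` (equals `center` to scan
#'   precision), `min_score`.
#' @export
make_ion_site_model <- function(center = c(0, 0, 0), r_oxy = 2.35, seed = 1L,
                                config = scorer_config(),
                                verify_spacing = 0.01) {
  set.seed(seed)
  rot <- stats::runif(1, 0, 2 * pi)
  rows <- list(); serial <- 0L
  add <- function(name, p, resname, resnum, element) {
    serial <<- serial + 1L
    rows[[serial]] <<- data.frame(
      serial = serial, name = name, altloc = "", resname = resname,
      chain = "A", resnum = resnum, icode = "",
      x = p[1], y = p[2], z = p[3], occ = 1, bfac = 0,
      element = element, record = "ATOM", stringsAsFactors = FALSE)
  }
  # three carboxylates on a cone below the equator (C3 about z): the open
  # top gives a single energy minimum on the +z axis above the cage centre
  theta <- 125 * pi / 180
  dphi <- asin(min(0.999, 1.1 / (r_oxy * sin(theta))))  # O-O chord 2.2 A
  sph <- function(th, ph) c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  for (j in 1:3) {
    phi <- rot + 2 * pi * (j - 1) / 3
    dirm <- sph(theta, phi)
    add("OD1", center + r_oxy * sph(theta, phi - dphi), "ASP", j, "O")
    add("OD2", center + r_oxy * sph(theta, phi + dphi), "ASP", j, "O")
    add("CG", center + (r_oxy + 1.25) * dirm, "ASP", j, "C")
    add("CB", center + (r_oxy + 2.75) * dirm, "ASP", j, "C")
    add("CA", center + (r_oxy + 4.25) * dirm, "ASP", j, "C")
  }
  model <- structure_model(do.call(rbind, rows),
                           model_id = sprintf("ionsite_seed%d", seed))
  scorer <- make_default_scorer(model, config)
  # locate the global minimum, checking it is unambiguous
  pos <- generate_grid(grid3d(center = center, extent = 2.0, spacing = 0.05))
  sc <- scorer$score_many(pos)
  argmin <- as.numeric(pos[which.min(sc), ])
  near <- pos[sc <= min(sc) + 0.05, , drop = FALSE]
  spread <- sqrt(rowSums((near - matrix(argmin, nrow(near), 3,
                                        byrow = TRUE))^2))
  if (max(spread) > 0.1)
    stop("generation error: degenerate ion-site minimum (near-optimal ",
         "positions spread over ", round(max(spread), 2), " A)")
  refined <- dense_scan(scorer, argmin, extent = 0.06,
                        spacing = verify_spacing)
  # translate the cage so the minimum sits at the requested center
  shift <- center - refined$position
  atoms <- model$atoms
  atoms$x <- atoms$x + shift[1]
  atoms$y <- atoms$y + shift[2]
  atoms$z <- atoms$z + shift[3]
  model <- structure_model(atoms, model_id = model$model_id)
  scorer <- make_default_scorer(model, config)
  check <- dense_scan(scorer, center, extent = 0.05,
                      spacing = verify_spacing)
  if (sqrt(sum((check$position - center)^2)) > 2 * verify_spacing)
    stop("generation error: minimum did not verify after translation")
  list(model = model, true_minimum = check$position,
       min_score = check$score)
}

#' Strip the coordinating oxygens from an ion-site model
#'
#' Removes the carboxylate oxygens but keeps the carbon scaffold: the bare
#' cage loses its electrostatic attraction yet still occludes first-shell
#' waters, so the site becomes less favourable than bulk solvent.
#'
#' @param site result of [make_ion_site_model] (or its `model`).
#' @return A [structure_model] without the OD1/OD2 atoms.
#' @export
strip_ion_site <- function(site) {
  model <- if (inherits(site, "structure_model")) site else site$model
  a <- model$atoms[!(model$atoms$name %in% c("OD1", "OD2")), , drop = FALSE]
  structure_model(a, model_id = paste0(model$model_id, "_stripped"))
}

#' Synthetic activity/energy tables with known linear structure
#'
#' Draws per-design energy differences uniformly over `ddg_range` and basal
#' activities from the linear relation
#' `BA = intercept + slope * ddG_apo + N(0, noise_sd)`, clipped into
#' (0.01, 0.99) with clip events counted. When `noise_sd` is `NULL` it is
#' calibrated to the realized design so the generating relation has
#' population correlation `r_target`:
#' `noise_sd = |slope| * sd(ddG) * sqrt(1/r_target^2 - 1)`.
#'
#' @param n_designs number of designs (default 14).
#' @param slope,intercept linear relation of basal activity on `ddG_apo`.
#' @param noise_sd Gaussian noise sd, or `NULL` to calibrate.
#' @param r_target target population correlation magnitude (default 0.91).
#' @param ddg_range uniform sampling interval for `ddG_apo` (REU).
#' @param seed integer seed.
#' @return list with `activity` (`design_id`, `basal_frac`, `induced_frac`,
#'   `sem`), `energy` (`design_id`, `dG_inactive`, `dG_active`,
#'   `ddG_apo`), `noise_sd`, `n_clipped`.
#' @export
make_activity_dataset <- function(n_designs = 14L, slope = -0.05,
                                  intercept = 0.25, noise_sd = NULL,
                                  r_target = 0.91, ddg_range = c(-4, 4),
                                  seed = 1L) {
  if (n_designs < 3L) stop("need at least 3 designs")
  set.seed(seed)
  ddg <- stats::runif(n_designs, ddg_range[1], ddg_range[2])
  if (is.null(noise_sd))
    noise_sd <- abs(slope) * stats::sd(ddg) * sqrt(1 / r_target^2 - 1)
  ba_raw <- intercept + slope * ddg + stats::rnorm(n_designs, 0, noise_sd)
  ba <- pmin(0.99, pmax(0.01, ba_raw))
  n_clipped <- sum(ba != ba_raw)
  ids <- sprintf("design_%02d", seq_len(n_designs))
  dg_inact <- stats::rnorm(n_designs, 0, 1)
  induced <- pmin(1.3, pmax(0.05, ba + stats::runif(n_designs, 0.3, 0.8)))
  list(activity = data.frame(design_id = ids, basal_frac = ba,
                             induced_frac = induced,
                             sem = stats::runif(n_designs, 0.01, 0.04),
                             stringsAsFactors = FALSE),
       energy = data.frame(design_id = ids, dG_inactive = dg_inact,
                           dG_active = dg_inact + ddg, ddG_apo = ddg,
                           stringsAsFactors = FALSE),
       noise_sd = noise_sd, n_clipped = n_clipped)
}

#' Write a planted fixture to disk
#'
#' Emits the standard triplet: PDB structure, annotation TSV and an
#' expected-values JSON side file.
#'
#' @param fixture result of [plant_water_network] or
#'   [random_planted_fixture] (must carry `annotation`).
#' @param dir output directory (created if needed).
#' @param name basename for the three files.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir, name = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, paste0(name, ".pdb"))
  ann <- file.path(dir, paste0(name, "_annotation.tsv"))
  js <- file.path(dir, paste0(name, "_expected.json"))
  write_structure(fixture$model, pdb)
  utils::write.table(fixture$annotation$table, ann, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(fixture$expected, js, auto_unbox = TRUE, digits = NA)
  invisible(c(pdb = pdb, annotation = ann, expected = js))
}
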