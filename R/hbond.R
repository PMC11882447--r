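# Donor/acceptor chemistry for standard residues. Roles follow textbook
# amino-acid chemistry at heavy-atom level; antecedent is the bonded heavy
# atom used for the hydrogen-free angle proxy.
.POLAR_SIDECHAIN <- list(
  SER = data.frame(name = "OG",  role = "both",     antecedent = "CB"),
  THR = data.frame(name = "OG1", role = "both",     antecedent = "CB"),
  TYR = data.frame(name = "OH",  role = "both",     antecedent = "CZ"),
  CYS = data.frame(name = "SG",  role = "both",     antecedent = "CB"),
  ASN = data.frame(name = c("OD1", "ND2"), role = c("acceptor", "donor"),
                   antecedent = c("CG", "CG")),
  GLN = data.frame(name = c("OE1", "NE2"), role = c("acceptor", "donor"),
                   antecedent = c("CD", "CD")),
  ASP = data.frame(name = c("OD1", "OD2"), role = "acceptor",
                   antecedent = c("CG", "CG")),
  GLU = data.frame(name = c("OE1", "OE2"), role = "acceptor",
                   antecedent = c("CD", "CD")),
  LYS = data.frame(name = "NZ",  role = "donor",    antecedent = "CE"),
  ARG = data.frame(name = c("NE", "NH1", "NH2"), role = "donor",
                   antecedent = c("CD", "CZ", "CZ")),
  HIS = data.frame(name = c("ND1", "NE2"), role = "both",
                   antecedent = c("CG", "CD2")),
  TRP = data.frame(name = "NE1", role = "donor",    antecedent = "CD1"),
  MET = data.frame(name = "SD",  role = "acceptor", antecedent = "CG")
)

.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

#' Polar-atom roles for a residue type
#'
#' Returns the hydrogen-bond donor/acceptor roles per heavy atom for one
#' residue type: backbone N (donor, except proline) and O/OXT (acceptor) for
#' standard amino acids, side-chain polar atoms per residue chemistry, and
#' water O as both donor and acceptor. Unknown residues without a custom
#' definition yield an empty table with a warning (treated as apolar).
#'
#' @param resname 3-letter residue code.
#' @param custom_defs optional data.frame (`resname`, `atomname`, `role`)
#'   with ligand polar-atom definitions, or a path to such a TSV.
#' @return data.frame with columns `name`, `role`
#'   (`donor`/`acceptor`/`both`), `antecedent` (may be `NA`).
#' @export
polar_atom_table <- function(resname, custom_defs = NULL) {
  if (is.character(custom_defs) && length(custom_defs) == 1L)
    custom_defs <- utils::read.table(custom_defs, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE)
  if (resname %in% .WATER_RESNAMES)
    return(data.frame(name = "O", role = "both", antecedent = NA_character_,
                      stringsAsFactors = FALSE))
  if (resname %in% .STANDARD_AA) {
    bb <- data.frame(
      name = c(if (resname != "PRO") "N", "O", "OXT"),
      role = c(if (resname != "PRO") "donor", "acceptor", "acceptor"),
      antecedent = c(if (resname != "PRO") "CA", "C", "C"),
      stringsAsFactors = FALSE)
    sc <- .POLAR_SIDECHAIN[[resname]]
    out <- if (is.null(sc)) bb else rbind(bb, sc)
    rownames(out) <- NULL
    return(out)
  }
  if (!is.null(custom_defs)) {
    hit <- custom_defs[custom_defs$resname == resname, , drop = FALSE]
    if (nrow(hit))
      return(data.frame(name = hit$atomname, role = hit$role,
                        antecedent = NA_character_, stringsAsFactors = FALSE))
  }
  warning("unknown residue '", resname, "' treated as apolar", call. = FALSE)
  data.frame(name = character(), role = character(), antecedent = character(),
             stringsAsFactors = FALSE)
}

#' Hydrogen-bond geometric criteria
#'
#' Heavy-atom distance window plus a hydrogen-free angle proxy evaluated at
#' the donor (antecedent-donor-acceptor angle); the proxy is skipped for
#' water donors. When explicit hydrogens are present on a donor, detection
#' is tightened by an H-acceptor distance cutoff.
#'
#' @param max_heavy_distance maximum donor-acceptor heavy-atom distance (A).
#' @param min_heavy_distance minimum heavy-atom distance (A).
#' @param min_angle_proxy minimum antecedent-donor-acceptor angle (degrees).
#' @param max_h_acceptor H-acceptor cutoff (A) used when hydrogens exist.
#' @return An `hbond_criteria` list.
#' @export
hbond_criteria <- function(max_heavy_distance = 3.5, min_heavy_distance = 2.4,
                           min_angle_proxy = 90, max_h_acceptor = 2.5) {
  if (!(min_heavy_distance > 0 && min_heavy_distance < max_heavy_distance))
    stop("require 0 < min_heavy_distance < max_heavy_distance")
  structure(list(max_heavy_distance = max_heavy_distance,
                 min_heavy_distance = min_heavy_distance,
                 min_angle_proxy = min_angle_proxy,
                 max_h_acceptor = max_h_acceptor),
            class = "hbond_criteria")
}

# Table of all polar atoms in a model: one row per polar heavy atom present,
# with coordinates, roles, antecedent coordinates and residue keys.
.polar_atoms <- function(model, custom_defs = NULL) {
  a <- model$atoms
  a <- a[a$element != "H", , drop = FALSE]
  a$rkey <- paste(a$chain, a$resnum, a$icode, sep = "|")
  out <- vector("list", 0L)
  warned <- character()
  for (rk in unique(a$rkey)) {
    res <- a[a$rkey == rk, , drop = FALSE]
    rn <- res$resname[1]
    tab <- withCallingHandlers(
      polar_atom_table(rn),
      warning = function(w) {
        if (rn %in% warned) invokeRestart("muffleWarning")
      })
    warned <- c(warned, rn)
    if (!nrow(tab)) next
    m <- match(tab$name, res$name)
    keep <- !is.na(m)
    if (!any(keep)) next
    tab <- tab[keep, , drop = FALSE]
    rows <- res[m[keep], , drop = FALSE]
    ant <- match(tab$antecedent, res$name)
    out[[length(out) + 1L]] <- data.frame(
      rkey = rk, chain = rows$chain, resnum = rows$resnum, icode = rows$icode,
      resname = rn, name = rows$name, kind = rows$kind,
      role = tab$role,
      x = rows$x, y = rows$y, z = rows$z,
      ax = ifelse(is.na(ant), NA_real_, res$x[ant]),
      ay = ifelse(is.na(ant), NA_real_, res$y[ant]),
      az = ifelse(is.na(ant), NA_real_, res$z[ant]),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(rkey = character(), chain = character(),
                      resnum = integer(), icode = character(),
                      resname = character(), name = character(),
                      kind = character(), role = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      ax = numeric(), ay = numeric(), az = numeric()))
  do.call(rbind, out)
}

# angle (degrees) at vertex b of points a-b-c; NA if undefined
.angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  cosang <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect hydrogen bonds in a structure
#'
#' Finds all unordered pairs of polar heavy atoms satisfying donor/acceptor
#' role compatibility and the geometric criteria: heavy-atom distance within
#' `[min_heavy_distance, max_heavy_distance]` (defaults 2.4-3.5 A) and,
#' hydrogen-free, an antecedent-donor-acceptor angle proxy of at least
#' `min_angle_proxy` (default 90 degrees; skipped when the donor is a
#' water). Intra-residue pairs are excluded. Each qualifying pair is
#' reported once.
#'
#' @param model a [structure_model].
#' @param criteria an [hbond_criteria] (defaults used when `NULL`).
#' @param custom_defs optional ligand polar-atom definitions (see
#'   [polar_atom_table]).
#' @return data.frame with one row per bond: residue keys, atom names, kinds
#'   (`water`/`residue` endpoints), `distance` and `angle_proxy`.
#' @export
find_hbonds <- function(model, criteria = NULL, custom_defs = NULL) {
  if (is.null(criteria)) criteria <- hbond_criteria()
  pa <- .polar_atoms(model, custom_defs)
  empty <- data.frame(rkey_a = character(), rkey_b = character(),
                      resname_a = character(), resname_b = character(),
                      name_a = character(), name_b = character(),
                      kind_a = character(), kind_b = character(),
                      distance = numeric(), angle_proxy = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(pa) < 2L) return(empty)
  xyz <- atom_xyz(pa)
  d <- as.matrix(stats::dist(xyz))
  cand <- which(upper.tri(d) & d >= criteria$min_heavy_distance &
                  d <= criteria$max_heavy_distance, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  # explicit hydrogens, if any, by residue (for the tightened H-acceptor check)
  h <- model$atoms[model$atoms$element == "H", , drop = FALSE]
  if (nrow(h)) h$rkey <- paste(h$chain, h$resnum, h$icode, sep = "|")
  can_donate <- pa$role %in% c("donor", "both")
  can_accept <- pa$role %in% c("acceptor", "both")
  keep <- logical(nrow(cand))
  ang_out <- rep(NA_real_, nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (pa$rkey[i] == pa$rkey[j]) next
    ok <- FALSE; best_ang <- NA_real_
    for (dir in list(c(i, j), c(j, i))) {
      don <- dir[1]; acc <- dir[2]
      if (!(can_donate[don] && can_accept[acc])) next
      if (pa$kind[don] == "water") { ok <- TRUE; break }
      ang <- NA_real_
      if (!is.na(pa$ax[don]))
        ang <- .angle_deg(c(pa$ax[don], pa$ay[don], pa$az[don]),
                          c(pa$x[don], pa$y[don], pa$z[don]),
                          c(pa$x[acc], pa$y[acc], pa$z[acc]))
      if (is.na(ang) || ang >= criteria$min_angle_proxy) {
        # hydrogen-aware tightening: if donor has bound H atoms, one must
        # be close enough to the acceptor
        if (nrow(h)) {
          hd <- h[h$rkey == pa$rkey[don], , drop = FALSE]
          if (nrow(hd)) {
            dh <- sqrt((hd$x - pa$x[don])^2 + (hd$y - pa$y[don])^2 +
                         (hd$z - pa$z[don])^2)
            hd <- hd[dh <= 1.3, , drop = FALSE]
            if (nrow(hd)) {
              dha <- sqrt((hd$x - pa$x[acc])^2 + (hd$y - pa$y[acc])^2 +
                            (hd$z - pa$z[acc])^2)
              if (min(dha) > criteria$max_h_acceptor) next
            }
          }
        }
        ok <- TRUE; best_ang <- ang; break
      }
    }
    keep[k] <- ok
    ang_out[k] <- best_ang
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  i <- cand[, 1]; j <- cand[, 2]
  data.frame(rkey_a = pa$rkey[i], rkey_b = pa$rkey[j],
             resname_a = pa$resname[i], resname_b = pa$resname[j],
             name_a = pa$name[i], name_b = pa$name[j],
             kind_a = ifelse(pa$kind[i] == "water", "water", "residue"),
             kind_b = ifelse(pa$kind[j] == "water", "water", "residue"),
             distance = d[cbind(i, j)],
             angle_proxy = ang_out[keep][seq_along(i)],
             stringsAsFactors = FALSE)
}
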