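#' @importFrom stats setNames
NULL

# Residue names recognized as water (PDB dialect variance).
.WATER_RESNAMES <- c("HOH", "WAT", "DOD")

#' Construct a structure model
#'
#' A `structure_model` holds the atoms of one coordinate model as a single
#' atom table plus optional metadata (a per-model energy in REU, the source
#' path). Waters are identified by residue name (`HOH`, `WAT`, `DOD` by
#' default) and carry `kind == "water"` in the atom table.
#'
#' @param atoms data.frame with columns `serial`, `name`, `altloc`, `resname`,
#'   `chain`, `resnum`, `icode`, `x`, `y`, `z`, `occ`, `bfac`, `element`,
#'   `record` ("ATOM"/"HETATM") and `kind` ("polymer"/"hetero"/"water").
#' @param model_id character scalar identifying the model.
#' @param energy optional model energy (REU); must be finite when present.
#' @param source optional source path.
#' @param water_names residue names treated as water.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = "model_1", energy = NULL,
                            source = NA_character_,
                            water_names = .WATER_RESNAMES) {
  required <- c("serial", "name", "altloc", "resname", "chain", "resnum",
                "icode", "x", "y", "z", "occ", "bfac", "element", "record")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure: model has zero atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (!is.null(energy) && !is.finite(energy)) stop("model energy must be finite")
  atoms$kind <- ifelse(atoms$resname %in% water_names, "water",
                       ifelse(atoms$record == "ATOM", "polymer", "hetero"))
  rownames(atoms) <- NULL
  structure(list(model_id = model_id, atoms = atoms,
                 energy = if (is.null(energy)) NULL else as.numeric(energy),
                 source = source),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  nw <- length(water_residues(x))
  np <- nrow(unique(x$atoms[x$atoms$kind != "water", c("chain", "resnum", "icode")]))
  cat(sprintf("structure_model '%s': %d atoms, %d polymer/hetero residues, %d waters%s\n",
              x$model_id, nrow(x$atoms), np, nw,
              if (!is.null(x$energy)) sprintf(", energy %.3f REU", x$energy) else ""))
  invisible(x)
}

# Unique residue keys "chain|resnum|icode" for waters.
water_residues <- function(model) {
  a <- model$atoms[model$atoms$kind == "water", , drop = FALSE]
  unique(paste(a$chain, a$resnum, a$icode, sep = "|"))
}

# Coordinates matrix (n x 3) for a subset of atom rows.
atom_xyz <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}

.validate_pdb_lines <- function(lines) {
  coord <- grep("^(ATOM  |HETATM)", lines)
  if (!length(coord)) stop("empty structure: no ATOM or HETATM records")
  for (i in coord) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("PDB parse error at line %d: coordinate record shorter than 54 columns", i))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop(sprintf("PDB parse error at line %d: non-numeric coordinate field", i))
  }
  invisible(TRUE)
}

#' Read a PDB structure
#'
#' Parses a PDB file into a [structure_model]. Waters are recognized by
#' residue name. Alternate locations are resolved by keeping, per atom name
#' within a residue, the altloc with the highest occupancy (ties broken by
#' alphabetical altloc id). Multi-`MODEL` files return the requested model.
#'
#' @param path path to a PDB file.
#' @param model model index for multi-MODEL files (default 1).
#' @param energy optional energy (REU) to attach to the model.
#' @param water_names residue names treated as water.
#' @return A [structure_model].
#' @export
read_structure <- function(path, model = 1L, energy = NULL,
                           water_names = .WATER_RESNAMES) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_lines(lines)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  a <- pdb$atom
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model < 1L || model > nmod)
    stop(sprintf("model index %d out of range (file has %d model(s))", model, nmod))
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  xyz <- matrix(xyz, ncol = 3L, byrow = TRUE)
  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    altloc = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
    resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    resnum = a$resno,
    icode = ifelse(is.na(a$insert) | a$insert == "", "", a$insert),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = ifelse(is.na(a$o), 1, a$o),
    bfac = ifelse(is.na(a$b), 0, a$b),
    element = trimws(ifelse(is.na(a$elesy), "", a$elesy)),
    record = a$type,
    stringsAsFactors = FALSE
  )
  blank <- atoms$element == ""
  if (any(blank)) atoms$element[blank] <- .guess_element(atoms$name[blank])
  atoms <- .resolve_altloc(atoms)
  structure_model(atoms, model_id = sprintf("%s#%d", basename(path), model),
                  energy = energy, source = path, water_names = water_names)
}

# Element from PDB atom-name convention (first alpha char, two-letter metals
# not needed for the atom types handled here).
.guess_element <- function(names) {
  el <- sub("^[0-9']*", "", names)
  substr(el, 1L, 1L)
}

# Keep, for each (chain, resnum, icode, atom name), the altloc of highest
# occupancy; ties broken by alphabetical altloc.
.resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$name, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resnum, atoms$icode,
                                   atoms$name, sep = "|")), , drop = FALSE]
  atoms[order(atoms$serial), , drop = FALSE]
}

#' Write a structure model to PDB
#'
#' Emits standard `ATOM`/`HETATM` records; waters are written as
#' `HETATM`/`HOH`. Coordinates are written to 3 decimals (PDB fixed format).
#'
#' @param model a [structure_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  if (nrow(a) == 0L) stop("refusing to write an empty model")
  rec <- ifelse(a$kind == "water", "HETATM", a$record)
  resname <- ifelse(a$kind == "water", "HOH", a$resname)
  ok <- tryCatch({
    suppressWarnings(bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(atom_xyz(a))),
      type = rec, resno = a$resnum, resid = resname,
      eleno = a$serial, elety = a$name, chain = a$chain,
      insert = ifelse(a$icode == "", NA, a$icode),
      o = a$occ, b = a$bfac, elesy = a$element))
    TRUE
  }, error = function(e) stop("I/O error writing ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Load a Ballesteros-Weinstein residue annotation
#'
#' Reads a TSV with columns `chain`, `resnum`, `bw`, `helix`, `class` mapping
#' author residue numbers to Ballesteros-Weinstein codes (`H.pos`), helix
#' index 1-7 (or `NA`), and helix class `static` / `switchable` / `none`.
#' Lines starting with `#` are skipped. Exact duplicate rows are
#' deduplicated; conflicting duplicates are an error.
#'
#' @param path TSV path.
#' @return A `bw_annotation`: the annotation table with a lookup method.
#' @export
load_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = c("character", "integer", "character",
                                         "integer", "character"),
                          col.names = c("chain", "resnum", "bw", "helix", "class"),
                          stringsAsFactors = FALSE, blank.lines.skip = TRUE)
  bw_annotation(df)
}

#' Build an annotation object from a data.frame
#'
#' @param df data.frame with columns `chain`, `resnum`, `bw`, `helix`, `class`.
#' @return A `bw_annotation` object.
#' @export
bw_annotation <- function(df) {
  if (nrow(df)) {
    bad <- !(df$class %in% c("static", "switchable", "none"))
    if (any(bad))
      stop("annotation class must be static/switchable/none; offending rows: ",
           paste(which(bad), collapse = ", "))
    okbw <- grepl("^[1-8]\\.[0-9]+$", df$bw)
    if (any(!okbw))
      stop("malformed BW code(s): ", paste(unique(df$bw[!okbw]), collapse = ", "))
    # helix id must agree with the BW prefix when both present
    pref <- as.integer(sub("\\..*$", "", df$bw))
    mism <- !is.na(df$helix) & df$helix != pref
    if (any(mism))
      stop("helix index inconsistent with BW prefix at rows: ",
           paste(which(mism), collapse = ", "))
    df <- unique(df)
    key <- paste(df$chain, df$resnum, sep = "|")
    if (anyDuplicated(key))
      stop("annotation conflict: duplicate (chain, resnum) with different values: ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  rownames(df) <- NULL
  structure(list(table = df), class = "bw_annotation")
}

#' Look up the annotation of one residue
#'
#' @param annotation a `bw_annotation`.
#' @param chain chain id.
#' @param resnum author residue number.
#' @return A one-row data.frame (`bw`, `helix`, `class`) or `NULL` on a miss.
#' @export
bw_lookup <- function(annotation, chain, resnum) {
  df <- annotation$table
  hit <- df$chain == chain & df$resnum == resnum
  if (!any(hit)) return(NULL)
  df[which(hit)[1], c("bw", "helix", "class")]
}

#' @export
print.bw_annotation <- function(x, ...) {
  cat(sprintf("bw_annotation: %d residues, helices %s\n", nrow(x$table),
              paste(sort(unique(stats::na.omit(x$table$helix))), collapse = ",")))
  invisible(x)
}

#' Build an ensemble of structure models
#'
#' @param models list of [structure_model] objects with unique `model_id`s.
#' @return An `ensemble` object.
#' @export
ensemble <- function(models) {
  if (!length(models)) stop("ensemble must contain at least one model")
  ids <- vapply(models, function(m) m$model_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate model_ids in ensemble")
  structure(list(models = models), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  e <- vapply(x$models, function(m) if (is.null(m$energy)) NA_real_ else m$energy,
              numeric(1))
  cat(sprintf("ensemble: %d models (%d with energies)\n",
              length(x$models), sum(!is.na(e))))
  invisible(x)
}

#' Read an ensemble from a manifest
#'
#' The manifest is a TSV `path<TAB>energy_REU` (header required); paths are
#' resolved relative to the manifest's directory.
#'
#' @param manifest_path manifest TSV path.
#' @return An `ensemble`.
#' @export
read_ensemble <- function(manifest_path) {
  df <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  names(df)[1:2] <- c("path", "energy_REU")
  base <- dirname(manifest_path)
  models <- lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!file.exists(p)) p <- file.path(base, df$path[i])
    read_structure(p, energy = df$energy_REU[i])
  })
  for (i in seq_along(models)) models[[i]]$model_id <- sprintf("%s#%d", basename(df$path[i]), i)
  ensemble(models)
}

#' Select the lowest-energy fraction of an ensemble
#'
#' Keeps the `ceiling(fraction * N)` lowest-energy models (never fewer than
#' one); ties are broken by input order. This is the ensemble reduction used
#' before consensus-water clustering.
#'
#' @param ens an `ensemble`; every model must carry an energy.
#' @param fraction fraction in (0, 1] (default 0.10).
#' @return An `ensemble` with the selected models, in ascending energy order.
#' @export
select_lowest_fraction <- function(ens, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  e <- vapply(ens$models, function(m) {
    if (is.null(m$energy) || !is.finite(m$energy))
      stop("missing energy for model ", m$model_id)
    m$energy
  }, numeric(1))
  k <- max(1L, as.integer(ceiling(fraction * length(e))))
  ord <- order(e)  # stable: ties keep input order
  ensemble(ens$models[ord[seq_len(k)]])
}
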