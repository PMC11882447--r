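# Minimal atom-table constructor for hand-built test models.
atom_row <- function(serial, name, resname, chain, resnum, xyz,
                     occ = 1, altloc = "", element = NULL,
                     record = if (resname %in% c("HOH", "WAT", "DOD"))
                       "HETATM" else "ATOM") {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  data.frame(serial = serial, name = name, altloc = altloc, resname = resname,
             chain = chain, resnum = resnum, icode = "",
             x = xyz[1], y = xyz[2], z = xyz[3], occ = occ, bfac = 0,
             element = element, record = record, stringsAsFactors = FALSE)
}

tiny_model <- function(...) {
  structure_model(do.call(rbind, list(...)), model_id = "tiny")
}

# A water-only model with oxygens at the given positions.
waters_model <- function(positions) {
  rows <- lapply(seq_len(nrow(positions)), function(i)
    atom_row(i, "O", "HOH", "W", i, positions[i, ]))
  tiny_model_list(rows)
}

tiny_model_list <- function(rows) {
  structure_model(do.call(rbind, rows), model_id = "tiny")
}

# An ensemble of single-water models at the given per-model positions.
water_ensemble <- function(pos_list) {
  models <- lapply(seq_along(pos_list), function(i) {
    pos <- pos_list[[i]]
    rows <- lapply(seq_len(nrow(pos)), function(j)
      atom_row(j, "O", "HOH", "W", j, pos[j, ]))
    m <- tiny_model_list(rows)
    m$model_id <- paste0("m", i)
    m$energy <- i
    m
  })
  ensemble(models)
}
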