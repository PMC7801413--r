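# Bead-model PDB I/O: one HETATM record per bead. Coordinates are written
# to 3 decimals; the per-bead weight is stored in the B-factor column
# after scaling into its fixed-width range (the scale factor is recorded
# in a REMARK so the round trip recovers weights), the bead radius in the
# occupancy column, and the component label in the chain identifier.

LABEL_TO_CHAIN <- c(dna_core = "D", dna_linker = "L", dna_unwrapped = "U",
                    histone_core = "H", h1_globular = "G", h1_ctd = "C")
ARM_TO_ICODE <- c(left = "l", right = "r")

#' Write a bead model as a PDB file
#'
#' @param model A [bead_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bead_pdb <- function(model, path) {
  if (!inherits(model, "bead_model")) stopf("`model` must be a bead_model")
  n <- nrow(model$positions)
  wscale <- 999.0 / max(model$weights)
  lines <- character(n + 3)
  lines[1] <- "REMARK   1 chromosaxs coarse-grained bead model"
  lines[2] <- sprintf("REMARK   2 WEIGHT_SCALE %.10e", wscale)
  arm <- ifelse(is.na(model$arm), " ", ARM_TO_ICODE[model$arm])
  chain <- LABEL_TO_CHAIN[model$labels]
  if (anyNA(chain)) stopf("model contains labels without a chain mapping")
  for (i in seq_len(n)) {
    lines[i + 2] <- sprintf(
      "HETATM%5d  C   BED %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      i %% 100000, chain[i], i %% 10000, arm[i],
      model$positions[i, 1], model$positions[i, 2], model$positions[i, 3],
      min(model$radii[i], 999.99), model$weights[i] * wscale)
  }
  lines[n + 3] <- "END"
  writeLines(lines, path)
  invisible(path)
}

#' Read a bead model from a PDB file written by [write_bead_pdb()]
#'
#' @param path PDB path.
#' @return A [bead_model()].
#' @export
read_bead_pdb <- function(path) {
  lines <- readLines(path)
  wscale <- NA_real_
  rem <- grep("^REMARK +2 WEIGHT_SCALE ", lines, value = TRUE)
  if (length(rem)) wscale <- as.numeric(sub(".*WEIGHT_SCALE +", "", rem[1]))
  at <- grep("^HETATM|^ATOM ", lines, value = TRUE)
  if (!length(at)) stopf("'%s': no atom records found", path)
  parse_num <- function(s, from, to) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    if (anyNA(v)) stopf("'%s': malformed coordinate/field in atom record", path)
    v
  }
  x <- parse_num(at, 31, 38); y <- parse_num(at, 39, 46); z <- parse_num(at, 47, 54)
  occ <- parse_num(at, 55, 60); b <- parse_num(at, 61, 66)
  chain <- substr(at, 22, 22)
  icode <- substr(at, 27, 27)
  labels <- names(LABEL_TO_CHAIN)[match(chain, LABEL_TO_CHAIN)]
  if (anyNA(labels)) stopf("'%s': unknown chain identifier in atom records", path)
  arm <- names(ARM_TO_ICODE)[match(icode, ARM_TO_ICODE)]
  weights <- if (is.finite(wscale)) b / wscale else b
  bead_model(cbind(x, y, z), weights, occ, labels, arm)
}
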