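## Shared fixture builders. Everything is generated in code; tests never
## read files except those they write themselves into tempdirs.

## compact retina phantom for unit tests (ONL 40 um tall)
small_retina_spec <- function(..., seed = 1L) {
  retina_phantom_spec(image_height_px = 240L, image_width_px = 128L,
                      layer_boundaries = c(12L, 40L, 120L, 150L),
                      ..., seed = seed)
}

## straight vertical sprout polyline for a given spec
straight_sprout <- function(spec, x_um, length_um, start_inside_um = 0.25) {
  opl_top_um <- (spec$layer_boundaries[3] - 1) * spec$pixel_size_um
  cbind(x_um = c(x_um, x_um),
        y_um = c(opl_top_um + start_inside_um,
                 opl_top_um + start_inside_um - length_um))
}

## 12-row peptide-evidence fixture with hand-annotated outcomes.
## Surviving proteins under the identification filters: PROT_A and PROT_F.
##  - PROT_B: one peptide fails the length rule (5 is not > 5) -> 1 left
##  - PROT_C: protein probability 99.0 is not > 99
##  - PROT_D: FDR 1.0 is not < 1
##  - PROT_E: one peptide singly charged, one at probability 80 (not > 80)
toy_peptide_table <- function() {
  data.frame(
    protein_id = c("PROT_A", "PROT_A", "PROT_B", "PROT_B", "PROT_C",
                   "PROT_C", "PROT_D", "PROT_D", "PROT_E", "PROT_E",
                   "PROT_F", "PROT_F"),
    peptide_sequence = sprintf("PEP%02d", 1:12),
    length_aa = c(8L, 12L, 5L, 10L, 9L, 11L, 8L, 7L, 9L, 10L, 7L, 9L),
    charge_state = c(2L, 3L, 2L, 2L, 2L, 3L, 2L, 2L, 1L, 2L, 2L, 2L),
    peptide_probability_pct = c(95, 85, 90, 90, 88, 93, 91, 96, 99, 80,
                                99, 92),
    protein_probability_pct = c(99.5, 99.5, 99.8, 99.8, 99.0, 99.0, 99.9,
                                99.9, 99.7, 99.7, 99.5, 99.5),
    protein_fdr_pct = c(0.5, 0.5, 0.3, 0.3, 0.4, 0.4, 1.0, 1.0, 0.2, 0.2,
                        0.2, 0.2),
    s1 = c(3, 1, 2, 4, 5, 6, 2, 3, 8, 1, 4, 2),
    s2 = c(4, 0, 1, 3, 4, 5, 2, 2, 7, 2, 3, 3),
    s3 = c(5, 2, 2, 5, 6, 4, 1, 4, 9, 1, 5, 1),
    s4 = c(6, 1, 3, 4, 5, 5, 3, 3, 6, 2, 4, 2),
    stringsAsFactors = FALSE
  )
}

toy_groups <- factor(c("WT", "WT", "KO", "KO"))

## write a gene-set collection in GMT format
write_gmt_file <- function(sets, path = tempfile(fileext = ".gmt")) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic set", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

## minimal dep_table stand-in for set-comparison tests
fake_dep_table <- function(ids, p = seq_along(ids) / (10 * length(ids))) {
  d <- data.frame(protein = ids, p_one_tail = p, FC = 2,
                  is_dep = TRUE, stringsAsFactors = FALSE)
  class(d) <- c("dep_table", "data.frame")
  d
}

## brute-force flood fill (4/8-connectivity) used as a labelling oracle
flood_fill_sizes <- function(mask) {
  mask <- mask > 0
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  sizes <- integer(0)
  for (r0 in seq_len(nrow(mask))) for (c0 in seq_len(ncol(mask))) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
            mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes)
}
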