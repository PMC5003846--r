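# small in-code fixtures shared across test files

hk5 <- c("ALG12", "GUSB", "RPLP0", "KRBA2", "ADAT2")
hk8 <- c(hk5, "DIRC1", "SLC26A3", "PHKG1")

# a tiny deterministic panel run: 3 endogenous, 2 housekeeping, 2 negatives
make_small_run <- function(n_samples = 2) {
  genes <- c("ACTB", "GUSB", "IRF1", "RPLP0", "ALG12", "NEG_A", "NEG_B")
  cls <- c("endogenous", "endogenous", "endogenous",
           "housekeeping", "housekeeping", "negative", "negative")
  base <- c(110, 250, 40, 500, 120, 8, 12)
  counts <- outer(base, seq_len(n_samples), function(b, j) b * j)
  dimnames(counts) <- list(genes, paste0("s", seq_len(n_samples)))
  panel_run(counts, cls,
            rep(c("untreated", "treated"), length.out = n_samples))
}

# write a minimal RCC file in the standard dialect
write_rcc_fixture <- function(path, rows, lane_id = 1) {
  lines <- c(
    "<Header>", "FileVersion,1.7", "SoftwareVersion,4.0.0.3", "</Header>",
    "<Sample_Attributes>", "ID,demo", "</Sample_Attributes>",
    "<Lane_Attributes>", paste0("ID,", lane_id), "FovCount,555",
    "</Lane_Attributes>",
    "<Code_Summary>", "CodeClass,Name,Accession,Count",
    rows,
    "</Code_Summary>")
  writeLines(lines, path)
  path
}

expect_setequal_sorted <- function(x, y) {
  testthat::expect_identical(sort(x), sort(y))
}
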