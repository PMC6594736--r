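# Small in-code fixtures shared across test files.

tiny_table <- function() {
  m <- matrix(c(5L, 3L,
                0L, 2L,
                1L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("OTU_1", "OTU_2", "OTU_3"), c("S1", "S2")))
  otu_table(m, taxonomy = c(
    OTU_1 = "k__Bacteria;p__Proteobacteria;c__Betaproteobacteria",
    OTU_2 = "k__Bacteria;p__Actinobacteria;c__Actinobacteria",
    OTU_3 = "k__Bacteria;p__Proteobacteria;c__Alphaproteobacteria"))
}

# deterministic neutral background used by several partition tests
neutral_background <- function(n_otus = 150, seed = 11) {
  simulate_metacommunity(
    metacommunity_scenario(n_otus = n_otus, seed = seed))$table
}

write_tiny_tsv <- function(path, dup_otu = FALSE, bad_count = NULL) {
  ids <- c("OTU_1", if (dup_otu) "OTU_1" else "OTU_2", "OTU_3")
  counts <- rbind(c(5, 3), c(0, 2), c(1, 0))
  if (!is.null(bad_count)) counts[1, 1] <- bad_count
  lines <- c(paste("#OTU ID", "S1", "S2", sep = "\t"),
             paste(ids, counts[, 1], counts[, 2], sep = "\t"))
  writeLines(lines, path)
  path
}
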