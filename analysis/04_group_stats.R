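#!/usr/bin/env Rscript
# Stage 4: community-structure statistics per ecological group -
# Adonis/ANOSIM/MRPP between the two simulated locations on
# Hellinger/Bray-Curtis distances, a Mantel test of community vs
# environmental distance, PCoA summaries, the abundance-occupancy
# regression, and the worked percentage arithmetic on the published
# 13-plant survey counts shipped with the package.

suppressMessages(library(asgroups))
dir.create("results/stats", showWarnings = FALSE, recursive = TRUE)

tab <- read_otu_table("results/tables/planted.tsv")
meta <- read_sample_metadata("results/tables/sample_metadata.tsv")
tab <- otu_table(tab$counts, metadata = meta)
labels <- read.delim("results/partition/labels.tsv")
grouping <- setNames(meta$location, rownames(meta))

groups <- Filter(function(v) length(v) >= 2, list(
  core = labels$otu_id[labels$cs_label == "core"],
  satellite = labels$otu_id[labels$cs_label == "satellite"],
  generalist = labels$otu_id[labels$gs_label == "generalist"],
  specialist = labels$otu_id[labels$gs_label == "specialist"]))

rows <- list(); pcoa_rows <- list()
for (g in names(groups)) {
  d <- bray_curtis(hellinger_transform(subset_otus(tab, groups[[g]])))
  for (tst in c("adonis", "anosim", "mrpp")) {
    fun <- switch(tst, adonis = adonis_test, anosim = anosim_test,
                  mrpp = mrpp_test)
    r <- fun(d, grouping, n_perm = 999, seed = 500 + match(g, names(groups)))
    rows[[paste(g, tst)]] <- data.frame(
      group = g, test = r$test_name, statistic = r$statistic,
      effect_r2 = r$effect_r2, p_value = r$p_value)
  }
  ord <- suppressWarnings(pcoa_ord(d))
  pcoa_rows[[g]] <- data.frame(
    group = g, axis1_pct = 100 * ord$proportion_explained[1],
    axis2_pct = 100 * ord$proportion_explained[2])
}
write.table(do.call(rbind, c(rows, make.row.names = FALSE)),
            "results/stats/structure_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, c(pcoa_rows, make.row.names = FALSE)),
            "results/stats/pcoa_axes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

denv <- dist(meta$env)
attr(denv, "Labels") <- rownames(meta)
mt <- mantel_test(bray_curtis(tab), denv, n_perm = 999, seed = 510)
message(sprintf("Mantel community vs environment: r = %.3f, P = %.3g",
                mt$statistic, mt$p_value))

ao <- abundance_occupancy(tab)
write.table(data.frame(slope = ao$slope, intercept = ao$intercept,
                       r_squared = ao$r_squared, p_value = ao$p_value,
                       n_otus = ao$n_otus, mantel_env_r = mt$statistic,
                       mantel_env_p = mt$p_value),
            "results/stats/abundance_occupancy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("abundance-occupancy: slope %.3f, R2 %.3f", ao$slope,
                ao$r_squared))

# worked percentages from the published survey counts
counts <- read.delim(system.file("extdata", "wwtp_group_counts.tsv",
                                 package = "asgroups"))
pub <- do.call(rbind, lapply(c("Bacteria", "Archaea"), function(dom) {
  total <- counts$n_otus[counts$domain == dom & counts$group == "total"]
  grp <- counts[counts$domain == dom & counts$group != "total", ]
  data.frame(domain = dom, group = grp$group, n_otus = grp$n_otus,
             pct_of_total = percentage(grp$n_otus, total))
}))
write.table(pub, "results/stats/published_group_percentages.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("published group percentages recomputed for ",
        nrow(pub), " domain/group combinations")
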