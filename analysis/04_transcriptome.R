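#!/usr/bin/env Rscript
# Transcriptome-wide spatial-similarity screen: correlate every gene's
# regional expression with the regional DT connectivity map, select the
# +/- 2 SD tails of the empirical (whole-transcriptome) null, and run
# overrepresentation of the lower tail against the annotation collection
# (Fisher's exact, fold enrichment > 2, Bonferroni q < 0.05).

suppressPackageStartupMessages(library(connectogene))

regional_t <- read_regional_map("results/regional_t_map.tsv")

spec <- synthetic_spec(n_genes = 2000, n_planted = 50, expr_noise_sd = 0.5,
                       seed = 42)
gen <- generate_expression(spec, regional_t)
utils::write.table(
  data.frame(gene = gen$planted),
  "results/planted_genes.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

res <- null_and_select(gene_similarity(gen$expr, regional_t), k_sd = 2)
print(res)
scores <- data.frame(gene = names(res$score), score = res$score,
                     tail = ifelse(names(res$score) %in% res$lower_tail, "lower",
                            ifelse(names(res$score) %in% res$upper_tail, "upper", "none")))
utils::write.table(scores, "results/similarity_scores.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("lower tail: %d genes (%d/%d planted recovered); upper tail: %d\n",
            length(res$lower_tail), sum(gen$planted %in% res$lower_tail),
            length(gen$planted), length(res$upper_tail)))

# distributed arm on the same transcriptome, then the overlap of the two
# candidate lists
regional_t_d <- read_regional_map("results/regional_t_map_distributed.tsv")
res_d <- null_and_select(gene_similarity(gen$expr, regional_t_d), k_sd = 2)
common <- shared_genes(res$lower_tail, res_d$lower_tail)
cat(sprintf("distributed lower tail: %d genes; shared with local list: %d\n",
            length(res_d$lower_tail), length(common)))

ann <- generate_annotations(gen$planted, gen$background, spec)
write_gmt(ann, "results/annotations.gmt")
enr <- overrepresentation(res$lower_tail, ann, fe_min = 2, q_max = 0.05)
utils::write.table(enr, "results/enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
sig <- enr[enr$significant, ]
cat(sprintf("%d enriched term(s); top: %s (FE = %.2f, q = %.2e)\n",
            nrow(sig), sig$term[1], sig$fold_enrichment[1], sig$q[1]))
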