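# small deterministic libraries used across tests

# n_genes genes x 3 guides with mutually distant synthetic spacers;
# first gene is a negative control
tiny_library <- function(n_genes = 4, seed = 7919L) {
  genes <- c("Neg1", paste0("Gene", seq_len(n_genes - 1)))
  roles <- c("negative_control", rep("candidate", n_genes - 1))
  specs <- tibble::tibble(
    gene = rep(genes, each = 3),
    role = rep(roles, each = 3),
    spacer = dualscreen::synthetic_spacers(3 * n_genes, seed = seed)
  )
  dualscreen::assemble_library(specs, guides_per_gene = 3, name = "tiny")
}

# one flow-counts row set built directly from gate counts
flow_fixture <- function(mpos_gpos, mpos_gneg, mneg_gpos, mneg_gneg,
                         guide_id = "sgX-1", gene = "X",
                         timepoint = "day7", replicate = 1L) {
  tibble::tibble(
    guide_id = guide_id, gene = gene, timepoint = timepoint,
    replicate = replicate,
    mcherry = c("pos", "pos", "neg", "neg"),
    gfp = c("pos", "neg", "pos", "neg"),
    events = c(mpos_gpos, mpos_gneg, mneg_gpos, mneg_gneg)
  )
}

# long-format two-sample count matrix for abundance scoring
count_fixture <- function(counts_pos, counts_neg, lineage = "HSPC") {
  lib_ids <- paste0("g", seq_along(counts_pos))
  dplyr::bind_rows(
    tibble::tibble(sample_id = paste0(lineage, "_GFPpos"),
                   lineage = lineage, gfp_gate = "pos",
                   guide_id = lib_ids, gene = lib_ids,
                   count = as.integer(counts_pos)),
    tibble::tibble(sample_id = paste0(lineage, "_GFPneg"),
                   lineage = lineage, gfp_gate = "neg",
                   guide_id = lib_ids, gene = lib_ids,
                   count = as.integer(counts_neg))
  )
}
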