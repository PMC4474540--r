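# hand-written 3-gene cohort used across io / diffexpr tests
tiny_cohort <- function() {
  expr <- matrix(c(1, 2, 3, 4,
                   5, 6, 7, 8,
                   0, 1, 0, 2), nrow = 3, byrow = TRUE,
                 dimnames = list(c("TP53", "PUF60", "BARD1"),
                                 c("s1T", "s1N", "s2T", "s2N")))
  pairs <- tibble::tibble(patient_id = c("p1", "p2"),
                          tumor_sample = c("s1T", "s2T"),
                          normal_sample = c("s1N", "s2N"))
  paired_cohort(expr, pairs, "TINY")
}

# random valid cohort for round-trip / oracle tests
random_cohort <- function(n_genes = 12, n_pairs = 4, seed = 1) {
  set.seed(seed)
  patients <- sprintf("p%02d", seq_len(n_pairs))
  expr <- matrix(rexp(n_genes * 2 * n_pairs, 1 / 50), n_genes,
                 dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                 c(paste0(patients, "T"), paste0(patients, "N"))))
  pairs <- tibble::tibble(patient_id = patients,
                          tumor_sample = paste0(patients, "T"),
                          normal_sample = paste0(patients, "N"))
  paired_cohort(expr, pairs, "RAND")
}

# a de_table built directly from chosen statistics, for unit fixtures
manual_de_table <- function(gene, log2fc, p_adj = rep(0.001, length(gene)),
                            is_de = rep(TRUE, length(gene)),
                            cohort_id = "C01", alpha = 0.05) {
  pandys:::new_de_table(
    tibble::tibble(gene = gene, mean_normal = 1, mean_tumor = 1,
                   log2fc = log2fc, t_stat = 0, df = 9,
                   p_raw = pmin(p_adj, 1), p_adj = p_adj, is_de = is_de),
    cohort_id = cohort_id, alpha = alpha, pseudocount = 1, n_pairs = 10)
}

# small but fully featured simulation config (fast: < 0.1 s per generate);
# any sim_config() argument can be overridden through ...
small_sim_config <- function(seed = 1, ...) {
  args <- list(
    n_cohorts = 3, n_genes = 400, n_pairs = 10,
    category_sizes = c(allOnco = 40, TF = 40, RBP = 40, lncRNA = 20),
    de_prob = c(allOnco = 0.3, TF = 0.1, RBP = 0.3, lncRNA = 0.1,
                other = 0.1),
    effect_scale = c(allOnco = 3, TF = 2, RBP = 1, lncRNA = 1.5,
                     other = 1.5),
    n_hub_rbps = 2, hub_neighbor_count = 12,
    tissue_set_size = 30,
    pathway_sizes = c(cell_cycle = 30, p53_signaling = 30),
    seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# members of every merge step, for comparing tree topologies
merge_members <- function(merge, labels) {
  rec <- function(node) {
    if (node < 0) return(labels[-node])
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  lapply(seq_len(nrow(merge)),
         function(s) paste(sort(rec(s)), collapse = ","))
}
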