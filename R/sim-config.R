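#' Simulation configuration
#'
#' Study conditions for the synthetic benchmark: a small multi-chromosome
#' host genome with annotated genes, planted repeat copies, germline
#' immune-receptor segments, an rDNA unit kept out of the host, and
#' divergent microbial genomes sharing no seed k-mer with any host-side
#' compartment, plus a labelled read mixture covering every protocol
#' category.
#'
#' @param seed Integer master seed; all substreams derive from it.
#' @param read_length Read length in bases.
#' @param n_reads Named integer vector of reads per truth class.  Classes:
#'   transcriptomic, mitochondrial, immune_locus, repeat, rdna, low_quality,
#'   low_complexity, lost_human, hyper_edited, ncl_circ, ncl_fusion,
#'   ncl_trans, immune_vj, microbial.
#' @param base_error_rate Per-base substitution sequencing-error rate
#'   applied after class construction (low-quality reads carry their own
#'   quality-driven corruption instead).
#' @param chromosome_length Length of each autosome-like chromosome.
#' @param mito_length Length of the mitochondrial contig.
#' @param repeat_copy_divergence Per-base substitution rate between a
#'   planted repeat copy and its consensus.
#' @param rdna_length Length of the rDNA repeating unit.
#' @param loci Immune loci to simulate.
#' @param n_v,n_j Germline V and J segments per locus.
#' @param v_length,j_length Segment lengths.
#' @param junction_insert_range Min/max random junction insert between the V
#'   and J portions of a V(D)J read.
#' @param v_overlap_range Min/max bases of V sequence at the start of a
#'   V(D)J read.
#' @param n_microbial Number of microbial genomes (up to 6 distinct taxa).
#' @param microbial_length_range Min/max microbial genome length.
#' @param hyper_edit_fraction Fraction of adenosines inside the cluster
#'   window converted to G in a hyper-edited read.
#' @param hyper_edit_window Cluster window as a fraction of read length.
#' @param hyper_edit_min_a Minimum adenosine count required in the window
#'   (fragments are redrawn until satisfied, emulating ADAR's preference
#'   for A-rich stretches and guaranteeing a dense cluster).
#' @param lost_human_edits Substitutions planted in lost-human reads
#'   (beyond the primary budget, within the sensitive budget).
#' @param low_quality_position_fraction Fraction of positions of a
#'   low-quality read drawn with Phred in `[2, 20]`.
#' @param homology_stress If `TRUE`, a copy of the host-absent repeat
#'   consensus is planted inside the first microbial genome, creating the
#'   controlled cross-compartment homology used by the step-order
#'   experiment.
#' @param k_reject k-mer length for cross-compartment rejection sampling.
#' @return A list of class `rop_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       read_length = 100,
                       n_reads = c(transcriptomic = 5800,
                                   mitochondrial = 100,
                                   immune_locus = 100,
                                   "repeat" = 800,
                                   rdna = 300,
                                   low_quality = 300,
                                   low_complexity = 200,
                                   lost_human = 300,
                                   hyper_edited = 400,
                                   ncl_circ = 200,
                                   ncl_fusion = 200,
                                   ncl_trans = 200,
                                   immune_vj = 400,
                                   microbial = 700),
                       base_error_rate = 0.005,
                       chromosome_length = 30000,
                       mito_length = 3000,
                       repeat_copy_divergence = 0.03,
                       rdna_length = 2000,
                       loci = c("IGK", "IGL", "TCRB"),
                       n_v = 6, n_j = 3,
                       v_length = 280, j_length = 60,
                       junction_insert_range = c(4, 12),
                       v_overlap_range = c(25, 55),
                       n_microbial = 6,
                       microbial_length_range = c(5000, 12000),
                       hyper_edit_fraction = 0.6,
                       hyper_edit_window = 0.75,
                       hyper_edit_min_a = 19,
                       lost_human_edits = 4,
                       low_quality_position_fraction = 0.8,
                       homology_stress = FALSE,
                       k_reject = 16) {
  full <- c(transcriptomic = 0, mitochondrial = 0, immune_locus = 0,
            "repeat" = 0, rdna = 0, low_quality = 0, low_complexity = 0,
            lost_human = 0, hyper_edited = 0, ncl_circ = 0, ncl_fusion = 0,
            ncl_trans = 0, immune_vj = 0, microbial = 0)
  unknown <- setdiff(names(n_reads), names(full))
  if (length(unknown)) stop("unknown read class: ", unknown[1])
  full[names(n_reads)] <- n_reads
  stopifnot(all(full >= 0), read_length >= 50,
            hyper_edit_fraction > 0, hyper_edit_fraction < 1,
            base_error_rate >= 0, base_error_rate < 1,
            chromosome_length >= 28000, n_microbial >= 1, n_microbial <= 6)
  structure(list(
    seed = as.integer(seed), read_length = as.integer(read_length),
    n_reads = full, base_error_rate = base_error_rate,
    chromosome_length = as.integer(chromosome_length),
    mito_length = as.integer(mito_length),
    repeat_copy_divergence = repeat_copy_divergence,
    rdna_length = as.integer(rdna_length),
    loci = loci, n_v = as.integer(n_v), n_j = as.integer(n_j),
    v_length = as.integer(v_length), j_length = as.integer(j_length),
    junction_insert_range = as.integer(junction_insert_range),
    v_overlap_range = as.integer(v_overlap_range),
    n_microbial = as.integer(n_microbial),
    microbial_length_range = as.integer(microbial_length_range),
    hyper_edit_fraction = hyper_edit_fraction,
    hyper_edit_window = hyper_edit_window,
    hyper_edit_min_a = as.integer(hyper_edit_min_a),
    lost_human_edits = as.integer(lost_human_edits),
    low_quality_position_fraction = low_quality_position_fraction,
    homology_stress = isTRUE(homology_stress),
    k_reject = as.integer(k_reject)
  ), class = "rop_sim_config")
}
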