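#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' spatial cutoff `r_c` (1.0 particle radii), Hi-C count threshold (250),
#' entangled relation set (parallel + cross), clustering split (0.02), scan
#' step (5 beads), smoothing window/degree (15 beads / 2), peak prominence
#' (0.2), convergence tolerance (0.05), barcode segments (4), expression
#' abundance floor (50 per Mb), binning (1 Mb), and seed. The configuration
#' is echoed into every run manifest.
#'
#' @param r_c spatial cutoff in particle radii.
#' @param hic_threshold Hi-C count threshold.
#' @param include_concerted include CP/CP_inv in the entangled set.
#' @param clustering_threshold high/low clustering split.
#' @param scan_step window increment in beads.
#' @param smooth_window,smooth_degree smoothing filter parameters.
#' @param prominence peak prominence threshold.
#' @param convergence_tol relative tolerance for fractal-trace convergence.
#' @param n_segments barcode segments.
#' @param abundance_floor expression floor per bin.
#' @param bin_bp sequence bin size in bp.
#' @param seed RNG seed for any stochastic stage.
#' @return list of class `ct_config`.
#' @export
ct_config <- function(r_c = 1.0, hic_threshold = 250,
                      include_concerted = FALSE,
                      clustering_threshold = 0.02, scan_step = 5L,
                      smooth_window = 15L, smooth_degree = 2L,
                      prominence = 0.2, convergence_tol = 0.05,
                      n_segments = 4L, abundance_floor = 50,
                      bin_bp = 1e6, seed = NULL) {
  cfg <- list(r_c = r_c, hic_threshold = hic_threshold,
              include_concerted = include_concerted,
              clustering_threshold = clustering_threshold,
              scan_step = scan_step, smooth_window = smooth_window,
              smooth_degree = smooth_degree, prominence = prominence,
              convergence_tol = convergence_tol, n_segments = n_segments,
              abundance_floor = abundance_floor, bin_bp = bin_bp,
              seed = seed)
  pos <- c("r_c", "hic_threshold", "clustering_threshold", "scan_step",
           "smooth_window", "smooth_degree", "prominence", "convergence_tol",
           "n_segments", "abundance_floor", "bin_bp")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("configuration value '", f, "' must be a positive number")
  }
  class(cfg) <- "ct_config"
  cfg
}

#' Run the full circuit-topology pipeline on one chain
#'
#' Composes the stages contacts -> topology matrix -> entanglement metrics
#' -> contact network -> fractal dimension -> cumulative scan -> L-pattern
#' profile, writing every stage output plus a manifest (with the full
#' configuration echo) to `out_dir`. Input is either a 3D bead chain or a
#' Hi-C count matrix; with Hi-C input the 3D-only stages (gyration radius)
#' are skipped.
#'
#' @param chain a [bead_chain], or `NULL` when `hic` is given.
#' @param hic a Hi-C count matrix (dense or COO data frame), or `NULL`.
#' @param expression optional [expression_track] for the correlation stage.
#' @param out_dir output directory (created if missing).
#' @param config a [ct_config].
#' @return (invisibly) a list with every stage result.
#' @export
run_pipeline <- function(chain = NULL, hic = NULL, expression = NULL,
                         out_dir, config = ct_config()) {
  stopifnot(inherits(config, "ct_config"))
  if (is.null(chain) && is.null(hic))
    stop("stage 'contacts' needs a chain or a Hi-C matrix as input")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ent <- entangled_set(config$include_concerted)

  contacts <- if (!is.null(chain)) {
    extract_contacts(chain, r_c = config$r_c)
  } else {
    contacts_from_hic(hic, threshold = config$hic_threshold)
  }
  write_contacts_tsv(contacts, file.path(out_dir, "contacts.tsv"),
                     chrom = if (!is.null(chain)) chain$label else "hic")
  if (n_contacts(contacts) < 2L)
    stop("stage 'topomat' needs at least 2 contacts; got ",
         n_contacts(contacts))

  m <- build_topology_matrix(contacts)
  write_topology_tsv(m, file.path(out_dir, "topology.tsv"))
  write_topology_tiff(m, file.path(out_dir, "topology.tif"))

  rows <- contact_entanglement(m, ent)
  trace <- site_entanglement_trace(contacts, rows)
  write_trace_tsv(trace, file.path(out_dir, "site_entanglement.tsv"))
  metrics <- list(n_contacts = n_contacts(contacts),
                  entangled_fraction = entangled_fraction(m, ent),
                  relation_counts = as.list(relation_counts(m)))
  if (!is.null(chain)) metrics$radius_of_gyration <- radius_of_gyration(chain)

  expr_cor <- NULL
  if (!is.null(expression)) {
    binned <- entanglement_by_bin(contacts, rows, bin_bp = config$bin_bp)
    write_trace_tsv(binned, file.path(out_dir, "binned_entanglement.tsv"))
    expr_cor <- correlate_with_expression(binned, expression,
                                          abundance_floor = config$abundance_floor)
    metrics$expression_r <- expr_cor$r
    metrics$expression_p <- expr_cor$p
  }

  g <- build_graph(contacts)
  write_graph_tsv(g, file.path(out_dir, "graph_edges.tsv"))
  net <- network_report(g)
  jsonlite::write_json(net, file.path(out_dir, "network.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  fr <- box_count_dimension(binarize_entangled(m, ent))
  fr$D_norm <- normalized_dimension(fr, n_contacts(contacts))
  write_fractal_json(fr, file.path(out_dir, "fractal.json"))

  scan <- cumulative_scan(contacts, metric = "entangled_fraction",
                          step = config$scan_step, entangled = ent)
  sm <- smooth_series(scan, window = config$smooth_window,
                      degree = config$smooth_degree)
  write_scan_tsv(scan, file.path(out_dir, "scan_entangled.tsv"), smoothed = sm)
  peaks <- find_peaks(sm, prominence = config$prominence)
  write_tsv_plain(data.frame(peak_window_beads = as.numeric(peaks)),
                  file.path(out_dir, "peaks.tsv"))

  lengths <- lpattern_lengths(m, ent)
  write_lprofile_tsv(lengths, file.path(out_dir, "lpattern_profile.tsv"))
  barcode <- segment_barcode(lengths, contacts, n_segments = config$n_segments)
  write_tsv_plain(data.frame(segment = seq_along(barcode), total = barcode),
                  file.path(out_dir, "barcode.tsv"))
  groups <- turn_groups(m)

  manifest <- list(package = "ctgenome",
                   version = as.character(utils::packageVersion("ctgenome")),
                   config = config[!vapply(config, is.null, logical(1))],
                   note = "bead indices in files are 1-based",
                   outputs = list.files(out_dir))
  jsonlite::write_json(c(manifest, list(metrics = metrics)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(contacts = contacts, topology = m, metrics = metrics,
                 trace = trace, expression = expr_cor, network = net,
                 fractal = fr, scan = scan, smoothed = sm, peaks = peaks,
                 lpattern_lengths = lengths, barcode = barcode,
                 turn_groups = groups))
}
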