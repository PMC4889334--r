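# Independent oracles and small fixture builders used across the suite.

# explicit-loop oracle for the exposed-epitope fraction: count epitopes
# whose last codon plus the tunnel offset has been translated
oracle_fraction <- function(x, epitopes, delta) {
  n <- 0
  for (e in epitopes) if (e + delta <= x) n <- n + 1
  n / length(epitopes)
}

oracle_mean_correction <- function(construct) {
  vals <- vapply(seq_len(construct$orf_length_codons), oracle_fraction,
                 numeric(1), epitopes = construct$epitope_positions,
                 delta = construct$exit_tunnel_codons)
  mean(vals)
}

default_construct <- function() reporter_preset("kif18b_suntag24")

random_construct <- function() {
  L <- sample(200:2000, 1)
  k <- sample(1:24, 1)
  eps <- sort(sample(seq_len(max(L - 50, k)), k))
  reporter_construct("random", L, eps, exit_tunnel_codons = sample(0:50, 1))
}

# noiseless trace of a single mRNA whose ribosome set is given per frame
trace_from_positions <- function(times, positions_list, construct,
                                 mrna_id = "m1") {
  tibble::tibble(
    mrna_id = mrna_id, time_s = times,
    green = vapply(positions_list, site_intensity, numeric(1),
                   construct = construct))
}

# roadblock runoff trace: one defective ribosome at codon `p` stalls from
# drug entry until `release_s`, queueing the ribosomes behind it while the
# ones ahead run off normally
make_roadblock_trace <- function(construct, p, release_s, n_rib = 15,
                                 k = 3.5, noise = 0.1, footprint = 10,
                                 entry_delay = 60, t_max = 2400) {
  L <- construct$orf_length_codons
  pos0 <- sort(sample(seq_len(L), n_rib))
  behind <- pos0 <= p
  queue_rank <- rev(seq_len(sum(behind))) - 1  # 0 for the stalled one itself
  times <- seq(-120, t_max, by = 30)
  g <- vapply(times, function(t) {
    dt <- max(0, t - entry_delay)
    pos <- pos0 + k * dt
    # behind-block ribosomes cannot pass the queue position until release
    cap <- p - footprint * queue_rank
    held <- pmin(pos0[behind] + k * dt, cap)
    extra <- max(0, t - entry_delay - release_s) * k
    pos[behind] <- pmin(held + extra, pos0[behind] + k * dt)
    pos <- pos[pos <= L]
    if (length(pos) == 0) 0 else site_intensity(pmax(pos, 1), construct)
  }, numeric(1))
  tibble::tibble(mrna_id = "rb", time_s = times,
                 green = g + rnorm(length(g), 0, noise))
}

# noiseless steady-buildup ensemble at a given initiation rate (per min)
make_buildup_ensemble <- function(construct, ki_per_min, n = 25,
                                  duration = 900, k_elong = 3.5) {
  purrr::map_dfr(seq_len(n), function(i) {
    tr <- simulate_translation(
      construct, kinetic_parameters(k_init = ki_per_min / 60,
                                    k_elong = k_elong),
      duration_s = duration, mrna_id = sprintf("m%03d", i))
    render_intensity_trace(tr, noise = c(0, 0))
  })
}
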