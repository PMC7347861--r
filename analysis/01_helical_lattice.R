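#!/usr/bin/env Rscript
# Helical-lattice arithmetic for the two archaeal type IV pili, from their
# refined symmetry parameters (rise 5.26 A / twist 101.69 deg and
# rise 4.97 A / twist 104.57 deg). Writes per-filament lattice tables and
# helical nets under results/.

suppressPackageStartupMessages(library(pilihelix))
dir.create("results", showWarnings = FALSE)

filaments <- list(
  par = helical_symmetry(5.26, 101.69),   # P. arsenaticum pilus
  sso = helical_symmetry(4.97, 104.57)    # S. solfataricus pilus
)

lattice <- do.call(rbind, lapply(names(filaments), function(nm) {
  sym <- filaments[[nm]]
  dom <- dominant_start_family(sym, 10)
  rr <- rational_repeat(sym, 100)
  data.frame(filament = nm, rise = sym$rise, twist = sym$twist,
             subunits_per_turn = subunits_per_turn(sym),
             subunits_in_two_turns = round_half_away(subunits_in_turns(sym, 2)),
             pitch = pitch(sym),
             dominant_start = dom$n,
             dominant_eff_twist = dom$eff_twist,
             dominant_handedness = dom$handedness,
             repeat_u = rr$u, repeat_t = rr$t,
             repeat_residual_deg = rr$residual)
}))
write.table(lattice, "results/lattice_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

message("Both filaments pack ~3.5 subunits per turn of the right-handed ",
        "1-start helix:")
message(sprintf("  %s: %.1f subunits in two turns, dominant %d-start is %s-handed",
                lattice$filament, lattice$subunits_in_two_turns,
                lattice$dominant_start, lattice$dominant_handedness))
message("The two lattices sit on opposite sides of 3.5 subunits/turn, which ",
        "is why the same 7-start family flips handedness between them.")

# start-family tables and unrolled helical nets (r = 40 A, a typical
# surface radius for an ~80 A filament; the display radius is a choice)
for (nm in names(filaments)) {
  write.table(start_family_table(filaments[[nm]], 10),
              sprintf("results/start_families_%s.tsv", nm), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(helical_net(filaments[[nm]], radius = 40, k = 0:27),
              sprintf("results/helical_net_%s.tsv", nm), sep = "\t",
              row.names = FALSE, quote = FALSE)
}

# selection rule: allowed Bessel orders on the first layer lines of the
# u-in-t-turns approximations
sel <- do.call(rbind, lapply(names(filaments), function(nm) {
  rr <- rational_repeat(filaments[[nm]], 100)
  do.call(rbind, lapply(0:10, function(l) {
    data.frame(filament = nm, layer_line = l, u = rr$u, t = rr$t,
               allowed_n = paste(allowed_bessel_orders(l, rr, 12),
                                 collapse = ","))
  }))
}))
write.table(sel, "results/selection_rule_orders.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("Wrote lattice_summary, start_families_*, helical_net_*, ",
        "selection_rule_orders to results/.")
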