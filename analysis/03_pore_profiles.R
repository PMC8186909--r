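#!/usr/bin/env Rscript

# Pore-radius profiles: calibration on constructed cylinder fixtures, then
# the gate-region profile of the synthetic closed-state channel model
# (all-atom and backbone-only), and a gate water count demonstration.

suppressMessages(library(mechanotraj))
dir.create("results", showWarnings = FALSE)

# calibration: the profiler must read back constructed radii
for (r0 in c(1, 3)) {
  cyl <- make_pore_cylinder(function(z) r0, axial_extent = c(-6, 6))
  prof <- pore_profile(cyl, z_range = c(-4, 4), z_step = 0.5)
  message(sprintf("cylinder r = %.1f A: profile %.2f-%.2f A", r0,
                  min(prof$radius), max(prof$radius)))
}

s <- synthetic_channel_model()
map <- synthetic_channel_map()
sel <- select_domain(s, map, "S6")
z_gate <- mean(s$xyz[select_domain(s, map, "gate_residue"), 3])

prof <- pore_profile(s, sel, z_range = z_gate + c(-12, 12), z_step = 1.2)
prof_bb <- pore_profile(s, sel, z_range = z_gate + c(-12, 12), z_step = 1.2,
                        backbone_only = TRUE)
m <- min_radius_near(prof, z_gate, 10)
message(sprintf("constriction: %.2f A at z = %.1f A (gate residue z = %.1f A)",
                m$radius, m$z, z_gate))

out <- data.frame(z_A = prof$z, radius_A = prof$radius,
                  radius_backbone_A = prof_bb$radius, status = prof$status)
write.table(out, "results/pore_profile_closed_model.tsv", sep = "\t",
            row.names = FALSE)

# waters in the gate cylinder: a wetting/dewetting bookkeeping demo
set.seed(1)
nw <- 30
wxyz <- cbind(runif(nw, -8, 8), runif(nw, -8, 8), z_gate + runif(nw, -10, 10))
watoms <- data.frame(serial = seq_len(nw), name = "OW", resname = "SOL",
                     chain = "W", resno = seq_len(nw), insert = "",
                     occupancy = 1, element = "O", stringsAsFactors = FALSE)
wet <- structure_new(rbind(s$atoms, watoms), rbind(s$xyz, wxyz))
n_in <- count_waters_in_gate(wet, gate_center = c(0, 0, z_gate),
                             radius = 4, half_height = 5)
message(n_in, " water oxygens inside the 4 A x 10 A gate cylinder")
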