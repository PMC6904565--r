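#!/usr/bin/env Rscript
# Generate the default synthetic xylem network and its observed flow map.
#
# The default spec emulates the census of a first-year grapevine
# internode: 491 vessels over a 10.4 mm2 annular cross-section, wider
# vessels in the dorsal/ventral wedges than in the lateral ones, pit-field
# and relay connections, and independent per-group pressure drops in the
# 0-0.78 kPa range observed for such stems. Outputs go to results/.

library(xylemflow)

seed <- 1
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_spec()
truth <- generate_synthetic_truth(spec, seed)

write_network(truth$network, file.path(out, "network.txt"))
write_flowmap(truth$noiseless, file.path(out, "flow_noiseless.csv"))
write_flowmap(truth$noisy, file.path(out, "flow_observed.csv"))
write.csv(truth$vessels, file.path(out, "vessels.csv"), row.names = FALSE)
write.csv(data.frame(group = seq_along(truth$true_drops_kPa),
                     true_drop_kPa = truth$true_drops_kPa),
          file.path(out, "true_drops.csv"), row.names = FALSE)

gr <- truth$groups
co <- truth$network$connections
cat(sprintf(
  "network: %d vessels, %d pit fields, %d relays, %d groups (%d solitary)\n",
  nrow(truth$vessels), sum(co$kind == "pit_field"),
  sum(co$kind == "relay_lumen"), max(gr$group),
  sum(table(gr$group) == 1)))
cat(sprintf("total top flow %.1f ug/s over %d nonzero pixels\n",
            total_top_flow(truth$solution),
            sum(truth$noiseless$values != 0)))
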