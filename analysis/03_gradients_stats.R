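#!/usr/bin/env Rscript
# Pressure-gradient statistics on the fitted per-group solution: axial and
# transverse gradient distributions, flow-weighted summaries, domain ANOVA,
# deviations from the idealized flow-radius curve, and the redirection of
# flow from wide to narrow vessels relative to a uniform-pressure fit.
#
# Requires results/ from 01-02 (re-created if absent).

library(xylemflow)

out <- "results"
if (!file.exists(file.path(out, "fit_summary.csv")))
  source("analysis/02_fit_scenarios.R")

network <- read_network(file.path(out, "network.txt"))
observed <- read_flowmap(file.path(out, "flow_observed.csv"))
vessels <- read.csv(file.path(out, "vessels.csv"))

fit_g <- fit_group_pressures(network, observed, upper = 2)
fit_u <- fit_uniform_pressure(network, observed)
v <- fit_g$vessels
w <- pmax(v$top_flow_ug_s, 0)

# flow-weighted axial gradient and radius
fw_grad <- flow_weighted_summary(v$gradient_MPa_m, w)
fw_rad <- flow_weighted_summary(vessels$radius_um, w)
cat(sprintf("flow-weighted axial gradient %.3f +/- %.3f MPa/m\n",
            fw_grad$mean, fw_grad$sd))
cat(sprintf("flow-weighted radius %.1f +/- %.1f um\n",
            fw_rad$mean, fw_rad$sd))

# transverse gradients between adjacent non-empty pixels at the top slice
grid <- default_grid(network, observed$pixel_size_um)
pm <- pixel_pressure_map(fit_g$solution, network, grid)
tg <- transverse_gradients(pm)
cat(sprintf("transverse gradients: n = %d, mean %.2f, median %.2f MPa/m\n",
            tg$n, tg$mean, tg$median))
write.csv(data.frame(gradient_MPa_m = tg$gradients_MPa_m),
          file.path(out, "transverse_gradients.csv"), row.names = FALSE)

# domain comparisons (vessel gradients and radii across radial and
# tangential domains, Type II two-way ANOVA)
an_g <- two_way_anova(v$gradient_MPa_m, vessels$radial, vessels$tangential)
an_r <- two_way_anova(vessels$radius_um, vessels$radial, vessels$tangential)
an_g$response <- "gradient"
an_r$response <- "radius"
write.csv(rbind(an_g, an_r), file.path(out, "domain_anova.csv"),
          row.names = FALSE)

# per-domain flow shares
share <- flow_share_report(fit_g$solution,
                           paste(vessels$radial, vessels$tangential, sep = "."))
write.csv(share, file.path(out, "flow_shares.csv"), row.names = FALSE)
print(share[, c("domain", "n_vessels", "flow_fraction")], digits = 3)

# deviations from the idealized flow-radius relationship
dev <- suppressWarnings(
  hp_deviation_test(vessels$radius_um, v$top_flow_ug_s, fw_grad$mean))
write.csv(dev, file.path(out, "hp_deviation.csv"), row.names = FALSE)
sig <- dev$center_radius_um[dev$p < 0.05]
if (length(sig))
  cat(sprintf("flows deviate from the idealized curve for windows at %d-%d um\n",
              min(sig), max(sig)))

# redirection of flow between the uniform and per-group scenarios
rd <- flow_redirection(fit_u, fit_g, vessels$radius_um)
cat(sprintf("redirected share %.1f%%; wide vessels lose %.1f%% of their uniform-fit flow\n",
            100 * rd$redirected_share, 100 * rd$wide_loss_fraction))
write.csv(rd$per_vessel, file.path(out, "redirection_per_vessel.csv"),
          row.names = FALSE)
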