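#!/usr/bin/env Rscript
# Does herbivore access reduce population growth? Plot-level stem totals
# (the size of the non-normalized kernel) compared by one-way ANOVA.

suppressMessages(library(estkernel))

stems <- read_stem_table("results/stem_table.csv")
g <- population_growth_anova(stems)
print(g)
write.csv(data.frame(statistic = c("mean_absent", "mean_present",
                                   "percent_reduction", "F", "df1", "df2",
                                   "p"),
                     value = c(g$means, g$percent_reduction, g$F, g$df, g$p)),
          "results/population_growth.csv", row.names = FALSE)
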