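synthetic 4-island SSR survey (generated by generate_island_fixture, seed 2024)
loc1
loc2
loc3
loc4
loc5
loc6
loc7
loc8
loc9
Pop
SantaCruz_1 , 112114 124124 132134 144146 156162 166166 176176 184188 192200
SantaCruz_2 , 112114 122124 132134 150150 158162 162166 176176 188188 192200
SantaCruz_3 , 112112 122124 134134 146146 162162 162164 176176 182188 192196
SantaCruz_4 , 112114 122124 134134 146146 152162 162166 172176 182182 192194
SantaCruz_5 , 114114 122124 000000 144146 152162 166166 172174 182184 192194
SantaCruz_6 , 112114 124124 132134 144144 158162 164166 176176 000000 192196
SantaCruz_7 , 112116 124124 134134 144146 158162 164164 174176 184184 192192
SantaCruz_8 , 112114 124124 132132 142144 162162 164164 172176 182188 196200
SantaCruz_9 , 114116 124124 132132 144144 162162 162164 176176 188188 192196
SantaCruz_10 , 114114 122124 132132 146146 158162 162166 176176 184188 194194
Pop
SanCristobal_1 , 116116 124124 132134 144150 154154 162166 176176 182184 198198
SanCristobal_2 , 112114 122124 134134 148148 154158 166166 000000 182182 194198
SanCristobal_3 , 112116 124124 132132 144144 154154 166166 176176 184188 198198
SanCristobal_4 , 114116 124124 132132 144148 154154 162166 176176 182184 200200
SanCristobal_5 , 112112 124124 132134 144144 154154 162164 176176 182184 198198
SanCristobal_6 , 114116 122124 134134 144144 154154 162164 176176 184188 194194
SanCristobal_7 , 112114 124124 134134 144148 154158 162164 176176 182184 194194
SanCristobal_8 , 114116 124124 134134 144144 154154 164164 176176 182182 194198
SanCristobal_9 , 112112 122124 132132 144150 154154 164166 176176 182188 198200
SanCristobal_10 , 114116 124124 134134 144148 152154 162162 172176 184188 194198
Pop
Isabela_1 , 112114 122124 132134 146146 158158 162166 176176 182188 192194
Isabela_2 , 114114 122124 132132 144150 158162 162166 176176 182182 198200
Isabela_3 , 112112 124124 132132 000000 162162 166166 172176 186188 194198
Isabela_4 , 114114 122124 132132 150150 154162 166166 172176 182188 192198
Isabela_5 , 114116 124124 132132 144144 158162 162166 172172 186186 194200
Isabela_6 , 114114 122124 132134 146146 158162 162166 176176 182188 192192
Isabela_7 , 114116 122124 132132 146150 162162 162162 172176 182182 198198
Isabela_8 , 114114 122124 132132 146146 162162 166166 172176 182188 192194
Isabela_9 , 114116 124124 132132 146150 158162 166166 172176 182182 192194
Isabela_10 , 112112 124124 132132 144146 156158 162166 172176 182182 192200
Pop
Floreana_1 , 112116 122122 132134 144150 158162 162162 172176 182182 194198
Floreana_2 , 112114 122122 132132 146150 152154 000000 176176 182182 192192
Floreana_3 , 112116 122124 132132 146146 154162 162166 172176 188188 198200
Floreana_4 , 114116 122124 132132 144146 158162 164164 176176 000000 192198
Floreana_5 , 114114 122122 132132 146146 154158 000000 172172 182182 192198
Floreana_6 , 112114 124124 132132 146150 156162 166166 176176 182182 192194
Floreana_7 , 112114 122124 132132 150150 158162 164166 172176 182188 194194
Floreana_8 , 112116 124124 132132 144150 152156 166166 176176 182182 192192
Floreana_9 , 116116 122124 132132 144144 156162 166166 176176 182186 192194
Floreana_10 , 112114 122122 132134 144150 158162 164166 000000 182182 192192
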