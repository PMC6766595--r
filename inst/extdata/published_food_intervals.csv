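food_id,food,group,hcc_inf,hcc_f,low,high
fruit_01,"Apples raw fuji with skin",fruit,3.85,3.84,3.73,3.97
fruit_02,"Apples raw gala with skin",fruit,3.87,3.87,3.78,3.96
fruit_03,"Apples raw golden delicious",fruit,3.86,3.86,3.78,3.94
fruit_04,"Apples raw granny smith with skin",fruit,3.87,3.87,3.79,3.96
fruit_05,"Apples raw red delicious with skin",fruit,3.85,3.85,3.75,3.96
fruit_06,"Blueberries raw",fruit,3.83,3.83,3.73,3.98
fruit_07,"Cherries sour red raw",fruit,3.82,3.82,3.75,3.92
fruit_08,"Clementines raw",fruit,3.92,3.91,3.79,4.01
fruit_09,"Currants red and white raw",fruit,3.91,3.92,3.79,4.09
fruit_10,"Dates deglet noor",fruit,3.86,3.86,3.75,3.96
fruit_11,"Dates medjool",fruit,3.78,3.78,3.73,3.84
fruit_12,"Figs dried uncooked",fruit,3.84,3.84,3.77,3.92
fruit_13,"Grapefruit raw pink and red all areas",fruit,3.91,3.90,3.76,4.08
fruit_14,"Grapes muscadine raw",fruit,3.89,3.89,3.82,3.95
fruit_15,"Grapes red or green raw European type",fruit,3.77,3.77,3.70,3.85
fruit_16,"Jackfruit raw",fruit,3.80,3.80,3.75,3.86
fruit_17,"Kiwi fruit green raw",fruit,3.85,3.85,3.74,3.97
fruit_18,"Lemon juice raw",fruit,3.85,3.84,3.69,3.98
fruit_19,"Lime juice raw",fruit,3.87,3.88,3.76,4.00
fruit_20,"Melons honeydew raw",fruit,3.86,3.85,3.69,4.01
fruit_21,"Nectarines raw",fruit,3.93,3.93,3.80,4.06
fruit_22,"Peaches yellow raw",fruit,3.91,3.92,3.81,4.03
fruit_23,"Pears raw",fruit,3.86,3.86,3.76,3.97
fruit_24,"Pears raw bartlett",fruit,3.86,3.86,3.75,3.97
fruit_25,"Pears raw bosc",fruit,3.88,3.88,3.75,4.03
fruit_26,"Pears raw green anjou",fruit,3.85,3.86,3.75,3.99
fruit_27,"Pears raw red anjou",fruit,3.85,3.85,3.74,3.98
fruit_28,"Pineapple raw all varieties",fruit,3.91,3.90,3.79,4.00
fruit_29,"Pineapple raw extra sweet variety",fruit,3.91,3.91,3.78,4.02
fruit_30,"Plums raw",fruit,3.83,3.83,3.72,3.94
fruit_31,"Rowal raw",fruit,4.00,4.00,3.94,4.06
veg_01,"Alfalfa seed sprouted raw",vegetable,4.07,4.08,3.93,4.25
veg_02,"Brussels sprouts raw",vegetable,4.02,4.02,3.94,4.10
veg_03,"Cabbage raw",vegetable,3.93,3.93,3.84,4.02
veg_04,"Cabbage red raw",vegetable,3.91,3.91,3.79,4.05
veg_05,"Carrots baby raw",vegetable,3.97,3.97,3.83,4.13
veg_06,"Carrots raw",vegetable,4.01,4.02,3.90,4.19
veg_07,"Cucumber with peel raw",vegetable,3.93,3.94,3.82,4.11
veg_08,"Lettuce green leaf raw",vegetable,4.00,4.00,3.87,4.16
veg_09,"Lettuce iceberg raw",vegetable,3.90,3.91,3.77,4.08
veg_10,"Mushrooms chanterelle raw",vegetable,4.05,4.05,3.97,4.14
veg_11,"Mushrooms maitake raw",vegetable,3.99,3.99,3.91,4.07
veg_12,"Mushrooms portabella raw",vegetable,3.88,3.87,3.74,4.06
veg_13,"Okra raw",vegetable,4.05,4.06,3.95,4.16
veg_14,"Onions raw",vegetable,3.89,3.90,3.79,4.01
veg_15,"Onions sweet raw",vegetable,3.83,3.83,3.74,3.94
veg_16,"Onions yellow sauteed",vegetable,3.89,3.89,3.77,4.02
veg_17,"Peppers jalapeno raw",vegetable,3.91,3.90,3.77,4.03
veg_18,"Peppers sweet green raw",vegetable,3.92,3.92,3.82,4.03
veg_19,"Peppers sweet red raw",vegetable,3.88,3.89,3.79,4.01
veg_20,"Radishes raw",vegetable,3.94,3.95,3.81,4.12
veg_21,"Rutabagas raw",vegetable,3.91,3.91,3.85,3.98
veg_22,"Spinach raw",vegetable,4.07,4.07,3.93,4.25
veg_23,"Squash summer zucchini includes skin raw",vegetable,3.87,3.87,3.74,4.04
veg_24,"Squash winter butternut raw",vegetable,3.95,3.95,3.88,4.02
cereal_01,"Amaranth grain uncooked",cereal,4.15,4.15,4.05,4.25
cereal_02,"Cornmeal degermed enriched white",cereal,4.14,4.14,4.04,4.25
cereal_03,"Pasta dry unenriched",cereal,4.15,4.15,4.06,4.24
cereal_04,"Pasta gluten-free corn and rice flour cooked",cereal,4.16,4.16,4.07,4.25
cereal_05,"Pasta whole-wheat cooked",cereal,4.15,4.15,4.06,4.24
cereal_06,"Potatoes flesh and skin raw",cereal,4.14,4.13,3.99,4.25
cereal_07,"Potatoes red flesh and skin raw",cereal,4.13,4.14,4.03,4.25
cereal_08,"Potatoes white flesh and skin raw",cereal,4.13,4.13,4.04,4.23
cereal_09,"Rice brown long-grain raw",cereal,4.16,4.16,4.07,4.25
cereal_10,"Rye flour light",cereal,4.12,4.11,3.99,4.25
cereal_11,"Rye grain",cereal,4.12,4.12,4.01,4.25
cereal_12,"Sorghum flour refined unenriched",cereal,4.09,4.09,4.00,4.18
cereal_13,"Spelt uncooked",cereal,4.13,4.13,4.02,4.25
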