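"item","subgroup","basis","energy_kcal_100g","protein_g_100g","carb_g_100g","lipid_g_100g"
"Rice","Rice, Wheat, Corn, and Others","consumed",284.595384,8.856354,47.181887,6.24425
"Bread","Rice, Wheat, Corn, and Others","consumed",284.595384,8.856354,47.181887,6.24425
"Spaghetti","Rice, Wheat, Corn, and Others","consumed",284.595384,8.856354,47.181887,6.24425
"Potato","Potatoes and Cassava","consumed",76,2.06,16.3,0.25
"Tomatoes","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Onion","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Lemon","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Carrot","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Avocado","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Corn","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Lettuce","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Sweet Pumpkin","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Bell Pepper","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Chard","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Zucchini","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Cucumber","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Green Beans","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Garlic","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Beetroot","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Spinach","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Cauliflower","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Artichoke","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Mushrooms","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Asparagus","All Types of Vegetables","consumed",45.516667,1.48,6.256667,1.623333
"Banana","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Apple","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Orange","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Peach and Nectarines","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Grapes","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Mandarins","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Strawberry","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Melons","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Pears","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Kiwi","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Watermelon","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Cherry","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Plum","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Prickly Pear","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Cucumber","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Mango","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Apricot","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Grapefruit","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Cherimoya","All Types of Fruits","consumed",59.393333,0.803333,13.55,0.68
"Whole Milk","Whole Milk or Equivalents","consumed",64,3.3,4.7,3.7
"Ground Beef","Beef, Lamb, and Pork","consumed",208.493933,25.553176,0,11.349036
"Pork Chop","Beef, Lamb, and Pork","consumed",208.493933,25.553176,0,11.349036
"Black Beef","Beef, Lamb, and Pork","consumed",208.493933,25.553176,0,11.349036
"Pork Pulp","Beef, Lamb, and Pork","consumed",208.493933,25.553176,0,11.349036
"Pork Ribs","Beef, Lamb, and Pork","consumed",208.493933,25.553176,0,11.349036
"Chicken Thigh","Chicken and Other Poultry","consumed",169.389866,26.783868,0.068942,6.377111
"Chicken Breast","Chicken and Other Poultry","consumed",169.389866,26.783868,0.068942,6.377111
"Whole Chicken","Chicken and Other Poultry","consumed",169.389866,26.783868,0.068942,6.377111
"Turkey Thigh","Chicken and Other Poultry","consumed",169.389866,26.783868,0.068942,6.377111
"Turkey Breast","Chicken and Other Poultry","consumed",169.389866,26.783868,0.068942,6.377111
"Ground Turkey","Chicken and Other Poultry","consumed",169.389866,26.783868,0.068942,6.377111
"Egg","Eggs","consumed",149,12.4,0.333333,10.933333
"Hake","Fish","consumed",121.928571,23.392857,0,2.392857
"Pomfret","Fish","consumed",121.928571,23.392857,0,2.392857
"Salmon","Fish","consumed",121.928571,23.392857,0,2.392857
"Dried Beans","Legumes","consumed",131.55,9.47,16.86,0.4
"Lentils","Legumes","consumed",131.55,9.47,16.86,0.4
"Vegetable Oil","Unsaturated Oils","consumed",829.25,0,0,92.2
"Olive Oil","Unsaturated Oils","consumed",829.25,0,0,92.2
"Butter","Saturated Oils","consumed",753.983051,0.59322,0.677966,83.220339
"Sugar","All Types of Sugars","consumed",393,0.096774,99.193548,0
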